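# Readers and writers for the external formats: GFF3 via rtracklayer,
# FASTA via Biostrings, TSV via readr, VCF (minimal biallelic writer;
# reader via vcfR), JSON truth tables via jsonlite.

#' Write an annotation tibble as GFF3
#'
#' Transcript rows become `transcript` features with exon children;
#' coordinates are emitted 1-based inclusive.
#'
#' @param annotation Annotation tibble (`id`, `type`, `chrom`, `strand`,
#'   `start`, `end`, `exons`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  tr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = "transcript", ID = annotation$id,
    biotype = annotation$type, source_tag = annotation$source)
  exl <- bind_rows(map2(annotation$exons, seq_len(nrow(annotation)),
                        function(e, i) tibble(chrom = annotation$chrom[i],
                                              start = e$start, end = e$end,
                                              strand = annotation$strand[i],
                                              parent = annotation$id[i])))
  ex <- GenomicRanges::GRanges(
    exl$chrom, IRanges::IRanges(exl$start, exl$end), strand = exl$strand,
    type = "exon", Parent = exl$parent)
  rtracklayer::export(c(tr, ex), path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 written by [write_gff3()] back into an annotation tibble
#'
#' @param path GFF3 path.
#' @return Annotation tibble with an `exons` list-column.
#' @export
read_gff3_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tr <- gr[gr$type == "transcript"]
  ex <- gr[gr$type == "exon"]
  parents <- as.character(unlist(ex$Parent))
  ex_tbl <- tibble(parent = parents,
                   start = GenomicRanges::start(ex),
                   end = GenomicRanges::end(ex))
  exl <- split(ex_tbl[, c("start", "end")], ex_tbl$parent)
  tibble(id = tr$ID,
         type = tr$biotype,
         source = tr$source_tag,
         chrom = as.character(GenomicRanges::seqnames(tr)),
         strand = as.character(GenomicRanges::strand(tr)),
         start = GenomicRanges::start(tr),
         end = GenomicRanges::end(tr),
         exons = map(tr$ID, ~ as_tibble(exl[[.x]]) |>
                       arrange(.data$start)))
}

#' Write sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read an expression matrix as TSV
#'
#' Wide TSV with a `transcript` id column; sample columns encode the design
#' in the `HN_L1` style (nitrogen, tissue initial, replicate), which
#' [read_expression_tsv()] parses back.
#'
#' @param x An [expression_matrix()].
#' @param path TSV path.
#' @return The path / an `expr_matrix`.
#' @export
write_expression_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x$values, rownames = "transcript"), path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param lengths Optional transcript lengths to attach on read.
#' @param unit Abundance unit tag.
#' @export
read_expression_tsv <- function(path, lengths = NULL, unit = "count") {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  sm <- stringr::str_match(colnames(m), "^(HN|LN)_([LR])(\\d+)$")
  if (anyNA(sm[, 1])) abort("sample columns must look like HN_L1")
  design <- tibble(sample = colnames(m),
                   tissue = ifelse(sm[, 3] == "L", "leaf", "root"),
                   nitrogen = sm[, 2],
                   replicate = as.integer(sm[, 4]))
  expression_matrix(m, design, lengths = lengths, unit = unit)
}

#' Write / read genotypes as VCF
#'
#' Minimal biallelic VCFv4.2 with GT calls (0/0, 0/1, 1/1, ./.); arbitrary
#' REF/ALT alleles. Reading goes through vcfR.
#'
#' @param geno A [genotype_matrix()].
#' @param path VCF path.
#' @return The path / a `geno_matrix`.
#' @export
write_genotypes_vcf <- function(geno, path) {
  gt <- matrix(c("0/0", "0/1", "1/1")[geno$dosage + 1],
               nrow(geno$dosage), ncol(geno$dosage))
  gt[is.na(geno$dosage)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$lines), collapse = "\t"))
  body <- vapply(seq_len(ncol(geno$dosage)), function(j) {
    paste(c(geno$map$chrom[j], geno$map$pos[j], geno$map$snp[j], "A", "G",
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- matrix(NA_real_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  dos[] <- t(ifelse(gt == "0/0", 0,
                    ifelse(gt %in% c("0/1", "1/0"), 1,
                           ifelse(gt == "1/1", 2, NA))))
  fix <- vcfR::getFIX(v)
  map <- tibble(snp = fix[, "ID"], chrom = fix[, "CHROM"],
                pos = as.numeric(fix[, "POS"]))
  genotype_matrix(dos, map)
}

#' Write / read a long phenotype table as TSV
#' @param phenotypes Long phenotype tibble.
#' @param path TSV path.
#' @return The path / a tibble.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(line = "c", treatment = "c",
                                          replicate = "i", trait = "c",
                                          value = "d"))
}

#' Write simulation truth tables as JSON
#' @param truth Truth list from [simulate_study()].
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
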