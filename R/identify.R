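# The five-step filter cascade turning assembled transcripts into lncRNA,
# TUCP and rejected classes, plus lincRNA/antisense classification against
# the known gene annotation.

.exon_granges <- function(ann) {
  ex <- bind_rows(map2(ann$exons, seq_len(nrow(ann)), function(e, i) {
    tibble(chrom = ann$chrom[i], start = e$start, end = e$end,
           strand = ann$strand[i], id = ann$id[i])
  }))
  GenomicRanges::GRanges(ex$chrom,
                         IRanges::IRanges(ex$start, ex$end),
                         strand = ex$strand, id = ex$id)
}

# ids of `query` transcripts whose exons overlap exons of `subject`
# transcripts; `same_strand = TRUE` requires equal strand, FALSE requires
# opposite strand. Self-pairs (same id) are ignored.
.exon_overlap_ids <- function(query, subject, same_strand) {
  if (nrow(query) == 0 || nrow(subject) == 0) return(character(0))
  gq <- .exon_granges(query)
  gs <- .exon_granges(subject)
  hits <- GenomicRanges::findOverlaps(gq, gs, ignore.strand = TRUE)
  qs <- as.character(GenomicRanges::strand(gq))[S4Vectors::queryHits(hits)]
  ss <- as.character(GenomicRanges::strand(gs))[S4Vectors::subjectHits(hits)]
  keep <- if (same_strand) qs == ss else qs != ss
  keep <- keep & gq$id[S4Vectors::queryHits(hits)] !=
    gs$id[S4Vectors::subjectHits(hits)]
  unique(gq$id[S4Vectors::queryHits(hits)][keep])
}

#' Classify lncRNAs as lincRNA or antisense
#'
#' A transcript is antisense when any of its exons overlaps any known gene
#' exon on the opposite strand; lincRNA otherwise (same-strand overlap was
#' removed earlier in the cascade).
#'
#' @param transcripts Annotation tibble of candidate lncRNAs (columns `id`,
#'   `chrom`, `strand`, `exons`).
#' @param known_annotation Annotation tibble of known genes.
#' @return Character vector (`"lincRNA"`/`"antisense"`) along `transcripts`.
#' @export
classify_lncrna <- function(transcripts, known_annotation) {
  anti <- .exon_overlap_ids(transcripts, known_annotation,
                            same_strand = FALSE)
  ifelse(transcripts$id %in% anti, "antisense", "lincRNA")
}

#' Run the five-step lncRNA identification filter cascade
#'
#' Applied in order: (1) length at least `min_length` nt; (2) expressed at
#' `min_fpkm` or more in at least `min_samples` samples; (3) no same-strand
#' exon overlap with a known coding gene; (4) composition call noncoding
#' (Fickett TESTCODE below `fickett_threshold`); (5) ORF call noncoding
#' (longest ORF below `orf_codons` codons). Failing exactly one of steps
#' 4/5 yields a transcript of uncertain coding potential (TUCP); failing
#' steps 1--3, or both 4 and 5, yields rejection with the first failing step
#' recorded; passing everything yields an lncRNA, classified lincRNA or
#' antisense.
#'
#' @param transcripts Annotation tibble of assembled transcripts.
#' @param sequences Named character vector of their sequences.
#' @param expression An [expression_matrix()] of abundances (FPKM scale for
#'   the default threshold) covering every transcript.
#' @param known_annotation Annotation tibble of known genes.
#' @param min_length Minimum transcript length (nt).
#' @param min_fpkm,min_samples Expression requirement.
#' @param orf_codons,fickett_threshold Coding-potential thresholds.
#' @return Tibble with columns `id`, `verdict` (`lncRNA`/`TUCP`/`rejected`),
#'   `rejection_step` (1--5 or `NA`), `lncrna_class`
#'   (`lincRNA`/`antisense`/`none`), plus the underlying `length`,
#'   `orf_codons` and `fickett_score`.
#' @export
run_filter_cascade <- function(transcripts, sequences, expression,
                               known_annotation,
                               min_length = 200, min_fpkm = 0.5,
                               min_samples = 1, orf_codons = 100,
                               fickett_threshold = 0.95) {
  stopifnot(is.data.frame(transcripts))
  ids <- transcripts$id
  if (!all(ids %in% names(sequences)))
    abort("inconsistent inputs: transcripts missing from `sequences`")
  if (!all(ids %in% rownames(expression$values)))
    abort("inconsistent inputs: transcripts missing from expression matrix")
  seqs <- sequences[ids]
  len <- nchar(seqs)

  pass1 <- len >= min_length
  ab <- expression$values[ids, , drop = FALSE]
  pass2 <- rowSums(ab >= min_fpkm) >= min_samples
  overl <- .exon_overlap_ids(transcripts, known_annotation,
                             same_strand = TRUE)
  pass3 <- !(ids %in% overl)
  cp <- call_coding_potential(seqs, orf_codons = orf_codons,
                              fickett_threshold = fickett_threshold)
  pass4 <- cp$composition_call == "noncoding"
  pass5 <- cp$orf_call == "noncoding"

  verdict <- rep("lncRNA", length(ids))
  step <- rep(NA_integer_, length(ids))
  fail123 <- !pass1 | !pass2 | !pass3
  first123 <- ifelse(!pass1, 1L, ifelse(!pass2, 2L, 3L))
  verdict[fail123] <- "rejected"
  step[fail123] <- first123[fail123]
  both45 <- pass1 & pass2 & pass3 & !pass4 & !pass5
  verdict[both45] <- "rejected"
  step[both45] <- 4L
  tucp <- pass1 & pass2 & pass3 & xor(pass4, pass5)
  verdict[tucp] <- "TUCP"
  step[tucp] <- ifelse(!pass4[tucp], 4L, 5L)

  out <- tibble(id = ids, verdict = verdict, rejection_step = step,
                lncrna_class = "none",
                length = unname(len),
                orf_codons = cp$orf_codons,
                fickett_score = cp$fickett_score)
  is_lnc <- out$verdict == "lncRNA"
  if (any(is_lnc)) {
    out$lncrna_class[is_lnc] <- classify_lncrna(
      transcripts[is_lnc, , drop = FALSE], known_annotation)
  }
  out
}
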