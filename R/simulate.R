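# Synthetic-data generator: seed-reproducible annotations, transcript
# sequences, expression counts, miRNAs with planted response elements,
# genotypes and phenotypes, each with a truth table for parameter-recovery
# tests. Defaults emulate the study design: maize seedlings, two tissues
# (leaf, root) x two nitrogen treatments (HN, LN) x three replicates, a
# 255-line association panel genotyped on ten chromosomes, and seventeen
# seedling traits.

#' The twelve-sample expression design
#'
#' Two tissues x two nitrogen treatments x `n_reps` replicates, with sample
#' ids in the `HN_L1` style.
#'
#' @param n_reps Replicates per tissue/treatment cell.
#' @return Tibble with columns `sample`, `tissue`, `nitrogen`, `replicate`.
#' @export
default_design <- function(n_reps = 3) {
  tidyr::expand_grid(nitrogen = c("HN", "LN"),
                     tissue = c("leaf", "root"),
                     replicate = seq_len(n_reps)) |>
    mutate(sample = paste0(.data$nitrogen, "_",
                           toupper(substr(.data$tissue, 1, 1)),
                           .data$replicate)) |>
    select("sample", "tissue", "nitrogen", "replicate")
}

#' The seventeen seedling trait names
#'
#' Shoot length, leaf number, primary root length, crown/seminal root
#' numbers, fresh/dry weights, total root length, surface area, average root
#' diameter, root volume, and the WinRhizo topology counts.
#'
#' @return Character vector of 17 trait abbreviations.
#' @export
maize_seedling_traits <- function() {
  c("SL", "LN", "PRL", "CRN", "SRN", "RFW", "SFW", "TPB", "LDW",
    "TDW", "TRL", "SA", "ARD", "RV", "Tips", "Forks", "Crossings")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study. Proportions are validated to
#' \[0, 1\]; with the default design the expression matrix has twelve
#' columns.
#'
#' @param seed Global seed; each generator stage derives its own seed from
#'   it via [stage_seed()].
#' @param n_chromosomes,chromosome_length Genome layout (bp).
#' @param n_genes,n_lincrna,n_antisense,n_coding_decoys Feature counts.
#'   Decoys are protein-coding transcripts the lncRNA filter must reject.
#' @param design Sample design tibble, see [default_design()].
#' @param de_fraction,log2fc_effect Fraction of transcripts with a planted
#'   condition effect and its size (log2 fold change, LN vs HN).
#' @param nb_dispersion Negative-binomial dispersion of simulated counts.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline count means.
#' @param n_mirna,mirna_length Mature miRNA count and length (20--24 nt).
#' @param mre_plan Optional tibble (`mirna`, `host`, `mismatches`, and
#'   optionally `tissue`) of miRNA response elements to plant; `NULL` lets
#'   [simulate_study()] build the default two-star topology (2 miRNAs,
#'   2 lncRNA decoys, 14 mRNA targets).
#' @param n_precursor_lncrnas How many extra lncRNAs carry a planted
#'   precursor-hairpin fragment (true positives for the homology filter).
#' @param n_lines,n_snps Association panel size and marker count.
#' @param maf_range Uniform sampling range of per-SNP allele frequencies.
#' @param missing_rate Bernoulli missing-genotype rate.
#' @param ld_decay_scale If non-`NULL`, haplotypes are generated with
#'   exponentially decaying linkage (correlation `exp(-d/scale)` between
#'   markers `d` bp apart); `NULL` gives independent markers.
#' @param qtl_spec Optional tibble (`snp`, `trait`, `ve`, `treatment`) of
#'   planted QTLs; `ve` is the fraction of genetic variance explained in the
#'   treatment where the QTL acts (default `"LN"`, so the tolerance index
#'   carries signal).
#' @param h2_target Broad-sense heritability of simulated traits.
#' @param n_reps Phenotype replicates per line per treatment.
#' @param traits Trait names to simulate.
#' @param de_transcripts Optional tibble (`transcript`, `tissue`, `log2fc`)
#'   overriding the random choice of planted expression effects.
#' @param n_qtl,qtl_ve,qtl_trait Used by [simulate_study()] to resolve QTLs
#'   placed next to planted differentially expressed genes.
#' @param qtl_isolation Radius (bp) around each QTL-linked gene kept free
#'   of other planted differentially expressed genes, so candidate windows
#'   have unambiguous truth.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 10, chromosome_length = 1e6,
                       n_genes = 200, n_lincrna = 40, n_antisense = 10,
                       n_coding_decoys = 20,
                       design = default_design(),
                       de_fraction = 0.1, log2fc_effect = 2,
                       nb_dispersion = 0.1,
                       baseline_meanlog = 4, baseline_sdlog = 1.5,
                       n_mirna = 2, mirna_length = 21,
                       mre_plan = NULL, n_precursor_lncrnas = 1,
                       n_lines = 255, n_snps = 2000,
                       maf_range = c(0.05, 0.5), missing_rate = 0.02,
                       ld_decay_scale = NULL,
                       qtl_spec = NULL, h2_target = 0.6, n_reps = 3,
                       traits = maize_seedling_traits(),
                       de_transcripts = NULL,
                       n_qtl = 0, qtl_ve = 0.2, qtl_trait = "CRN",
                       qtl_isolation = 1.2e5) {
  cfg <- as.list(environment())
  props <- c(de_fraction = de_fraction, missing_rate = missing_rate)
  if (any(props < 0 | props > 1)) abort("proportions must lie in [0, 1]")
  if (h2_target < 0 || h2_target >= 1) abort("h2_target must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    abort("maf_range must lie within (0, 0.5]")
  if (mirna_length < 20 || mirna_length > 24)
    abort("mature miRNA length must be 20-24 nt")
  if (n_lines < 2) abort("need at least two lines")
  cfg$design <- as_tibble(design)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d | %d chrom x %g bp | %d genes, ",
                     "%d lincRNA, %d antisense, %d decoys | %d samples | ",
                     "%d lines x %d SNPs\n"),
              x$seed, x$n_chromosomes, x$chromosome_length, x$n_genes,
              x$n_lincrna, x$n_antisense, x$n_coding_decoys,
              nrow(x$design), x$n_lines, x$n_snps))
  invisible(x)
}

# ---- annotation + sequences -------------------------------------------------

# Draw a multi-exon structure totalling close to `target_len` transcribed bp.
.exon_structure <- function(n_exons, exon_range = c(100, 400),
                            intron_range = c(60, 300)) {
  ex <- round(runif(n_exons, exon_range[1], exon_range[2]))
  intr <- if (n_exons > 1) round(runif(n_exons - 1, intron_range[1],
                                       intron_range[2])) else integer(0)
  list(exon = ex, intron = intr, span = sum(ex) + sum(intr))
}

.place_exons <- function(start, ex, intr) {
  starts <- start + cumsum(c(0, head(ex, -1) + intr))
  tibble(start = starts, end = starts + ex - 1)
}

#' Simulate a gene/lncRNA annotation with transcript sequences
#'
#' Genes are multi-exon, strand-assigned and mutually non-overlapping; each
#' antisense lncRNA lies within exactly one gene's span on the opposite
#' strand and overlaps its first exon; lincRNAs and coding decoys are
#' intergenic. Noncoding transcripts carry no ORF of 60+ codons; decoys
#' carry a 100+ codon ORF with coding-like composition. Coordinates are
#' 1-based inclusive, ready for GFF3.
#'
#' @param config A [sim_config()].
#' @return List with `annotation` (tibble: `id`, `type`, `source`, `chrom`,
#'   `strand`, `start`, `end`, `exons` list-column), `sequences` (named
#'   character vector, length = summed exon length) and `truth` (planted
#'   type per transcript).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "annotation"))
  n_chr <- config$n_chromosomes
  chroms <- paste0("chr", seq_len(n_chr))
  counts <- function(n) tabulate(rep(seq_len(n_chr), length.out = n), n_chr)
  g_per <- counts(config$n_genes)
  li_per <- counts(config$n_lincrna)
  de_per <- counts(config$n_coding_decoys)

  rows <- list()
  seqs <- character(0)
  gid <- 0; lid <- 0; did <- 0
  for (ci in seq_len(n_chr)) {
    # genes: spans first, then random gaps filling the chromosome
    ng <- g_per[ci]
    structs <- map(seq_len(max(ng, 0)), ~ .exon_structure(sample(2:6, 1)))
    spans <- map_dbl(structs, "span")
    # intergenic features need room too: reserve slots between genes
    n_slots <- li_per[ci] + de_per[ci]
    slot_len <- 2000
    need <- sum(spans) + n_slots * slot_len + (ng + n_slots + 1) * 50
    if (need > config$chromosome_length)
      abort("genome too small: cannot place features without overlap")
    slack <- config$chromosome_length - need
    gaps <- diff(c(0, sort(runif(ng, 0, slack)))) + 50
    gstart <- cumsum(gaps) + cumsum(c(0, head(spans, -1)))
    gene_rows <- vector("list", ng)
    for (gi in seq_len(ng)) {
      gid <- gid + 1
      ex <- .place_exons(round(gstart[gi]), structs[[gi]]$exon,
                         structs[[gi]]$intron)
      id <- sprintf("GENE_%04d", gid)
      tl <- sum(ex$end - ex$start + 1)
      utr5 <- max(12, round(tl * 0.08)); utr3 <- max(12, round(tl * 0.12))
      n_cod <- (tl - utr5 - utr3) %/% 3
      body <- coding_orf(max(n_cod, 40))
      pad <- tl - utr5 - nchar(body)
      sq <- paste0(strip_long_orfs(random_dna(utr5)), body,
                   if (pad > 0) strip_long_orfs(random_dna(pad)) else "")
      sq <- substr(sq, 1, tl)
      gene_rows[[gi]] <- tibble(id = id, type = "gene", source = "known",
                                chrom = chroms[ci],
                                strand = sample(c("+", "-"), 1),
                                start = min(ex$start), end = max(ex$end),
                                exons = list(ex))
      seqs[id] <- sq
    }
    gene_tbl <- bind_rows(gene_rows)
    rows[[length(rows) + 1]] <- gene_tbl

    # intergenic slots: gaps between consecutive gene spans (and the tail)
    occ_start <- if (nrow(gene_tbl)) gene_tbl$start else numeric(0)
    occ_end <- if (nrow(gene_tbl)) gene_tbl$end else numeric(0)
    ord <- order(occ_start)
    bounds <- tibble(lo = c(1, occ_end[ord] + 25),
                     hi = c(occ_start[ord] - 25, config$chromosome_length))
    bounds <- bounds |> filter(.data$hi - .data$lo >= slot_len)
    placed <- tibble(start = numeric(0), end = numeric(0))
    place_intergenic <- function(len) {
      for (try in 1:200) {
        b <- bounds[sample(nrow(bounds), 1), ]
        st <- round(runif(1, b$lo, b$hi - len))
        en <- st + len - 1
        clash <- any(placed$start <= en & placed$end >= st)
        if (!clash) {
          placed <<- bind_rows(placed, tibble(start = st, end = en))
          return(c(st, en))
        }
      }
      abort("genome too small: intergenic placement failed")
    }
    for (k in seq_len(li_per[ci])) {
      lid <- lid + 1
      n_ex <- sample(1:3, 1)
      st <- .exon_structure(n_ex, exon_range = c(150, 600),
                            intron_range = c(60, 200))
      # lncRNAs are >= 200 nt by definition; pad the first exon if needed
      if (sum(st$exon) < 200) {
        st$exon[1] <- st$exon[1] + (200 - sum(st$exon))
        st$span <- sum(st$exon) + sum(st$intron)
      }
      pos <- place_intergenic(st$span)
      ex <- .place_exons(pos[1], st$exon, st$intron)
      id <- sprintf("LINC_%04d", lid)
      tl <- sum(ex$end - ex$start + 1)
      rows[[length(rows) + 1]] <- tibble(
        id = id, type = "lincRNA", source = "assembled", chrom = chroms[ci],
        strand = sample(c("+", "-"), 1),
        start = min(ex$start), end = max(ex$end), exons = list(ex))
      seqs[id] <- noncoding_seq(tl)
    }
    for (k in seq_len(de_per[ci])) {
      did <- did + 1
      len <- round(runif(1, 600, 1500))
      pos <- place_intergenic(len)
      id <- sprintf("DECOY_%04d", did)
      rows[[length(rows) + 1]] <- tibble(
        id = id, type = "decoy", source = "assembled", chrom = chroms[ci],
        strand = sample(c("+", "-"), 1),
        start = pos[1], end = pos[2],
        exons = list(tibble(start = pos[1], end = pos[2])))
      seqs[id] <- coding_decoy_seq(len)
    }
  }
  ann <- bind_rows(rows)

  # antisense: inside a gene span, opposite strand, overlapping exon 1
  genes <- ann |> filter(.data$type == "gene")
  if (config$n_antisense > nrow(genes))
    abort("genome too small: more antisense lncRNAs than genes")
  hosts <- genes[sample(nrow(genes), config$n_antisense), ]
  as_rows <- vector("list", config$n_antisense)
  for (k in seq_len(config$n_antisense)) {
    h <- hosts[k, ]
    ex1 <- h$exons[[1]][1, ]
    len <- min(round(runif(1, 200, 600)), h$end - ex1$start + 1)
    st <- ex1$start
    id <- sprintf("ASLNC_%04d", k)
    as_rows[[k]] <- tibble(
      id = id, type = "antisense", source = "assembled", chrom = h$chrom,
      strand = if (h$strand == "+") "-" else "+",
      start = st, end = st + len - 1,
      exons = list(tibble(start = st, end = st + len - 1)))
    seqs[id] <- noncoding_seq(len)
  }
  ann <- bind_rows(ann, bind_rows(as_rows)) |>
    arrange(.data$chrom, .data$start)
  truth <- ann |> select("id", "type")
  list(annotation = ann, sequences = seqs, truth = truth)
}

# ---- expression -------------------------------------------------------------

#' Simulate negative-binomial expression counts with planted effects
#'
#' Baseline per-transcript count means are log-normal; a planted subset has
#' its mean multiplied by `2^log2fc` in the LN samples of the designated
#' tissue. Counts are negative binomial at `nb_dispersion`.
#'
#' @param annotation Output of [simulate_annotation()] (the list or just its
#'   `annotation` tibble plus `sequences` names).
#' @param config A [sim_config()]. `config$de_transcripts`, when set,
#'   overrides the random choice of planted effects.
#' @return List with `expression` (an [expression_matrix()] of counts) and
#'   `truth` (tibble `transcript`, `tissue`, `log2fc` of planted effects).
#' @export
simulate_expression <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- if (is.list(annotation) && !is.data.frame(annotation))
    annotation$annotation else annotation
  set.seed(stage_seed(config$seed, "expression"))
  design <- config$design
  if (nrow(design) == 0) abort("design must be non-empty")
  if (config$nb_dispersion <= 0) abort("nb_dispersion must be positive")
  ids <- ann$id
  n <- length(ids)
  lengths <- setNames(map_dbl(ann$exons, ~ sum(.x$end - .x$start + 1)), ids)
  baseline <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  names(baseline) <- ids

  truth <- config$de_transcripts
  if (is.null(truth)) {
    n_de <- floor(config$de_fraction * n)
    if (config$de_fraction > 0 && n_de < 1)
      abort("configuration conflict: de_fraction selects no transcript")
    pick <- sample(ids, n_de)
    truth <- tibble(
      transcript = pick,
      tissue = sample(unique(design$tissue), n_de, replace = TRUE),
      log2fc = sample(c(-1, 1), n_de, replace = TRUE) * config$log2fc_effect)
  } else {
    truth <- as_tibble(truth)
    if (!all(truth$transcript %in% ids))
      abort("de_transcripts refers to unknown transcripts")
  }
  # a planted effect must be expressed to be a planted effect: floor the
  # baseline of planted transcripts at the log-normal median
  if (nrow(truth) > 0) {
    idx <- match(truth$transcript, ids)
    baseline[idx] <- pmax(baseline[idx], exp(config$baseline_meanlog))
  }
  # planted ceRNA hub members are abundant, tightly regulated transcripts:
  # high baseline and low dispersion, so their shared response pattern
  # dominates and the co-expression they are planted with is real
  disp <- rep(config$nb_dispersion, n)
  precise <- config$precise_transcripts %||% character(0)
  if (length(precise)) {
    pidx <- match(intersect(precise, ids), ids)
    disp[pidx] <- config$precise_dispersion %||% 0.01
    baseline[pidx] <- pmax(baseline[pidx], exp(config$baseline_meanlog + 1))
  }

  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(ids, design$sample))
  for (j in seq_len(nrow(design))) {
    mu <- baseline
    if (design$nitrogen[j] == "LN" && nrow(truth) > 0) {
      hit <- truth |> filter(.data$tissue == design$tissue[j])
      idx <- match(hit$transcript, ids)
      mu[idx] <- mu[idx] * 2^hit$log2fc
    }
    counts[, j] <- rnbinom(n, mu = mu, size = 1 / disp)
  }
  expr <- expression_matrix(counts, design, lengths = lengths, unit = "count")
  list(expression = expr, truth = truth)
}

# ---- miRNAs and response elements ------------------------------------------

.mutate_base <- function(base, avoid) {
  sample(setdiff(c("A", "C", "G", "T"), c(base, avoid)), 1)
}

#' Simulate mature miRNAs and plant response elements into host transcripts
#'
#' For each plan entry, the reverse complement of the mature miRNA — with the
#' requested number of mismatches introduced outside miRNA positions 10--11,
#' preserving cleavage-site complementarity — is spliced into the host
#' sequence at a recorded position. A designated set of lncRNAs additionally
#' receives a planted precursor-hairpin fragment so the precursor-homology
#' filter has true positives. A small miRNA count matrix with planted
#' differential expression for the plan miRNAs is emitted as well.
#'
#' @param config A [sim_config()].
#' @param sequences Named character vector of host transcript sequences.
#' @param mre_plan Tibble (`mirna` index or name, `host`, `mismatches`,
#'   optional `tissue`); defaults to `config$mre_plan`, possibly empty.
#' @param precursor_hosts Character vector of lncRNA ids to tag with a
#'   precursor fragment (default: none).
#' @return List with `mature`, `precursors` (named character vectors),
#'   `sequences` (hosts with planted sites), `counts` (an
#'   [expression_matrix()] of miRNA counts) and `truth` (list: `mre`,
#'   `precursor`, `de_mirna`).
#' @export
simulate_mirna <- function(config, sequences, mre_plan = NULL,
                           precursor_hosts = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "mirna"))
  L <- config$mirna_length
  mature <- setNames(
    vapply(seq_len(config$n_mirna), function(i) random_dna(L), character(1)),
    sprintf("ZmmiR-sim%02d", seq_len(config$n_mirna)))

  plan <- mre_plan %||% config$mre_plan %||%
    tibble(mirna = character(0), host = character(0), mismatches = integer(0))
  plan <- as_tibble(plan)
  if (nrow(plan) > 0) {
    if (is.numeric(plan$mirna)) plan$mirna <- names(mature)[plan$mirna]
    if (!all(plan$host %in% names(sequences)))
      abort("mre plan refers to unknown host transcripts")
    if (any(plan$mismatches >= L))
      abort("invalid spec: mismatches exceed miRNA length")
    if (!"tissue" %in% names(plan)) plan$tissue <- "leaf"
  } else plan$tissue <- character(0)

  occupied <- list()
  mre_truth <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    m <- mature[[plan$mirna[k]]]
    host <- plan$host[k]
    site <- revcomp(m)
    nm <- plan$mismatches[k]
    if (nm > 0) {
      cand <- setdiff(seq_len(L), 10:11)   # miRNA positions
      at <- sample(cand, nm)
      for (p in at) {
        sp <- L - p + 1                    # site position (5'->3' on target)
        base <- substr(site, sp, sp)
        mb <- substr(m, p, p)
        # a true mismatch: neither complementary nor a G:U wobble partner
        wob <- switch(mb, G = "T", T = "G", U = "G", NA_character_)
        substr(site, sp, sp) <- .mutate_base(base, wob)
      }
    }
    hseq <- sequences[[host]]
    if (nchar(hseq) < L + 2) abort("host transcript shorter than the miRNA site")
    occ <- occupied[[host]] %||% tibble(start = numeric(0), end = numeric(0))
    pos <- NA
    for (try in 1:100) {
      cand_pos <- sample(nchar(hseq) - L + 1, 1)
      if (!any(occ$start <= cand_pos + L - 1 & occ$end >= cand_pos)) {
        pos <- cand_pos; break
      }
    }
    if (is.na(pos)) abort("could not place response element in host")
    substr(hseq, pos, pos + L - 1) <- site
    sequences[[host]] <- hseq
    occupied[[host]] <- bind_rows(occ, tibble(start = pos, end = pos + L - 1))
    mre_truth[[k]] <- tibble(mirna = plan$mirna[k], host = host,
                             position = pos, mismatches = nm,
                             tissue = plan$tissue[k])
  }
  mre_truth <- bind_rows(mre_truth)
  if (nrow(mre_truth) == 0)
    mre_truth <- tibble(mirna = character(0), host = character(0),
                        position = integer(0), mismatches = integer(0),
                        tissue = character(0))

  # precursor hairpins, planted into designated lncRNAs
  precursors <- character(0)
  prec_truth <- vector("list", length(precursor_hosts))
  for (k in seq_along(precursor_hosts)) {
    host <- precursor_hosts[k]
    if (!host %in% names(sequences)) abort("unknown precursor host")
    mi <- names(mature)[(k - 1) %% length(mature) + 1]
    hairpin <- paste0(mature[[mi]], random_dna(12), revcomp(mature[[mi]]))
    hseq <- sequences[[host]]
    if (nchar(hseq) < nchar(hairpin) + 2)
      abort("precursor host too short for hairpin")
    pos <- sample(nchar(hseq) - nchar(hairpin) + 1, 1)
    substr(hseq, pos, pos + nchar(hairpin) - 1) <- hairpin
    sequences[[host]] <- hseq
    pid <- paste0(mi, "-hairpin")
    precursors[pid] <- hairpin
    prec_truth[[k]] <- tibble(lncrna = host, mirna = mi, precursor = pid)
  }
  prec_truth <- bind_rows(prec_truth)
  if (nrow(prec_truth) == 0)
    prec_truth <- tibble(lncrna = character(0), mirna = character(0),
                         precursor = character(0))

  # miRNA counts over the same design, planted DE (down in LN) for plan
  # miRNAs in their designated tissue
  design <- config$design
  base <- rlnorm(length(mature), 6, 1)
  counts <- matrix(0L, length(mature), nrow(design),
                   dimnames = list(names(mature), design$sample))
  de_mirna <- plan |> distinct(.data$mirna, .data$tissue) |>
    mutate(log2fc = -config$log2fc_effect)
  for (j in seq_len(nrow(design))) {
    mu <- base
    if (design$nitrogen[j] == "LN" && nrow(de_mirna) > 0) {
      hit <- de_mirna |> filter(.data$tissue == design$tissue[j])
      idx <- match(hit$mirna, names(mature))
      mu[idx] <- mu[idx] * 2^hit$log2fc
    }
    counts[, j] <- rnbinom(length(mature), mu = mu,
                           size = 1 / config$nb_dispersion)
  }
  mir_expr <- expression_matrix(counts, design, unit = "count")
  list(mature = mature, precursors = precursors, sequences = sequences,
       counts = mir_expr,
       truth = list(mre = mre_truth, precursor = prec_truth,
                    de_mirna = de_mirna))
}

# ---- genotypes --------------------------------------------------------------

#' Simulate a biallelic SNP panel
#'
#' Per-SNP allele frequencies are uniform on `maf_range`; dosages are
#' binomial(2) per line, with optional exponentially decaying linkage along
#' each chromosome (`ld_decay_scale`), Bernoulli missingness, and sorted map
#' positions per chromosome.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  n_chr <- config$n_chromosomes
  per <- tabulate(rep(seq_len(n_chr), length.out = config$n_snps), n_chr)
  lines <- sprintf("L%03d", seq_len(config$n_lines))
  n_hap <- 2L * config$n_lines
  dos <- NULL; maps <- list()
  for (ci in seq_len(n_chr)) {
    m <- per[ci]
    if (m == 0) next
    pos <- sort(sample.int(config$chromosome_length, m))
    p <- runif(m, config$maf_range[1], config$maf_range[2])
    if (is.null(config$ld_decay_scale)) {
      d <- vapply(seq_len(m), function(j) rbinom(config$n_lines, 2, p[j]),
                  numeric(config$n_lines))
    } else {
      # two haplotypes per line from a binary Markov chain whose adjacent
      # correlation is exp(-distance/scale); chain correlations multiply,
      # so r2 between markers d bp apart decays as exp(-2 d / scale)
      hap <- matrix(0L, n_hap, m)
      hap[, 1] <- as.integer(runif(n_hap) < p[1])
      if (m > 1) for (j in 2:m) {
        r <- exp(-(pos[j] - pos[j - 1]) / config$ld_decay_scale)
        cv <- r * sqrt(p[j - 1] * (1 - p[j - 1]) * p[j] * (1 - p[j]))
        p11 <- min(1, max(0, p[j] + cv / p[j - 1]))
        p10 <- min(1, max(0, p[j] - cv / (1 - p[j - 1])))
        u <- runif(n_hap)
        hap[, j] <- as.integer(ifelse(hap[, j - 1] == 1L, u < p11, u < p10))
      }
      d <- hap[seq_len(config$n_lines), , drop = FALSE] +
        hap[config$n_lines + seq_len(config$n_lines), , drop = FALSE]
    }
    if (config$missing_rate > 0)
      d[runif(length(d)) < config$missing_rate] <- NA
    snps <- sprintf("S_%s_%07d", paste0("chr", ci), pos)
    colnames(d) <- snps
    dos <- if (is.null(dos)) d else cbind(dos, d)
    maps[[ci]] <- tibble(snp = snps, chrom = paste0("chr", ci), pos = pos)
  }
  rownames(dos) <- lines
  genotype_matrix(dos, bind_rows(maps))
}

# ---- phenotypes -------------------------------------------------------------

#' Simulate replicated seedling phenotypes under two nitrogen treatments
#'
#' Per line, treatment and replicate: a treatment mean, treatment-specific
#' QTL effects (so the low-nitrogen tolerance index carries signal), a
#' polygenic term drawn once per line from a multivariate normal with
#' covariance proportional to the realized genomic kinship, and replicate
#' noise scaled so the broad-sense heritability of line means equals
#' `h2_target` in each treatment.
#'
#' @param geno A [genotype_matrix()].
#' @param config A [sim_config()]; `config$qtl_spec` is a tibble with
#'   columns `snp` (id or column index), `trait`, `ve` (fraction of genetic
#'   variance explained) and optional `treatment` (default `"LN"`).
#' @return List with `phenotypes` (long tibble: `line`, `treatment`,
#'   `replicate`, `trait`, `value`) and `truth` (list: `qtl`, `h2`).
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "phenotypes"))
  qtl <- config$qtl_spec
  if (!is.null(qtl) && nrow(qtl) > 0) {
    qtl <- as_tibble(qtl)
    if (is.numeric(qtl$snp)) qtl$snp <- colnames(geno$dosage)[qtl$snp]
    if (!all(qtl$snp %in% colnames(geno$dosage)))
      abort("qtl_spec refers to unknown SNPs")
    if (!"treatment" %in% names(qtl)) qtl$treatment <- "LN"
    bad <- qtl |> group_by(.data$trait) |>
      summarise(v = sum(.data$ve), .groups = "drop")
    if (any(bad$v >= 1))
      abort("invalid spec: QTL variance explained sums to >= 1")
  } else qtl <- tibble(snp = character(0), trait = character(0),
                       ve = numeric(0), treatment = character(0))

  n <- nrow(geno$dosage)
  lines <- geno$lines
  h2 <- config$h2_target
  r <- config$n_reps
  W <- impute_dosage(geno)
  K <- kinship(geno)
  A <- psd_sqrt(K)
  treatments <- c("HN", "LN")
  out <- vector("list", length(config$traits))
  for (ti in seq_along(config$traits)) {
    trait <- config$traits[ti]
    tq <- qtl |> filter(.data$trait == !!trait)
    ve_sum <- sum(tq$ve)
    poly <- if (h2 > 0) as.vector(A %*% rnorm(n)) * sqrt(max(0, 1 - ve_sum))
            else rep(0, n)
    mu_hn <- runif(1, 5, 50)
    mu <- c(HN = mu_hn, LN = mu_hn * runif(1, 0.75, 1.05))
    recs <- vector("list", 2)
    for (tr in treatments) {
      g <- poly
      tq_tr <- tq |> filter(.data$treatment == tr)
      for (qi in seq_len(nrow(tq_tr))) {
        w <- W[, tq_tr$snp[qi]]
        sw <- sd(w)
        if (sw > 0) g <- g + sqrt(tq_tr$ve[qi]) * (w - mean(w)) / sw
      }
      vg <- var(g)
      sigma_e <- if (vg > 0 && h2 > 0) sqrt(r * vg * (1 / h2 - 1)) else 1
      vals <- rep(mu[[tr]] + g, each = r) + rnorm(n * r, 0, sigma_e)
      recs[[tr]] <- tibble(line = rep(lines, each = r), treatment = tr,
                           replicate = rep(seq_len(r), times = n),
                           trait = trait, value = vals)
    }
    out[[ti]] <- bind_rows(recs)
  }
  list(phenotypes = bind_rows(out),
       truth = list(qtl = qtl,
                    h2 = tibble(trait = config$traits, h2 = h2)))
}

# ---- whole-study orchestration ---------------------------------------------

#' Simulate a complete coherent study
#'
#' Chains the annotation, expression, miRNA, genotype and phenotype
#' generators with coherent cross-links: a default two-star miRNA response
#' element plan (2 miRNAs, 2 lncRNA decoys, 14 mRNA targets) whose members
#' are all planted as differentially expressed; a precursor-tagged lncRNA;
#' and, when `config$n_qtl > 0`, low-nitrogen-specific QTLs placed at the
#' markers nearest to planted differentially expressed genes, so the
#' association and integration stages have recoverable truth.
#'
#' @param config A [sim_config()].
#' @return List with `annotation`, `sequences`, `expression`, `mirna`,
#'   `genotypes`, `phenotypes` and a `truth` list covering every planted
#'   effect.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- simulate_annotation(config)
  set.seed(stage_seed(config$seed, "study-plan"))
  anno <- ann$annotation
  lincs <- anno |> filter(.data$type == "lincRNA")
  genes <- anno |> filter(.data$type == "gene")

  # QTL-linked genes are chosen first; genes inside their future candidate
  # windows (an isolation radius around each) are kept out of every other
  # planted-DE set, so window contents have unambiguous truth
  qtl_genes <- tibble(gene = character(0), chrom = character(0),
                      mid = numeric(0))
  isolated_gene_ids <- character(0)
  if (config$n_qtl > 0) {
    pick <- genes[sample(nrow(genes), config$n_qtl), ]
    qtl_genes <- tibble(gene = pick$id, chrom = pick$chrom,
                        mid = (pick$start + pick$end) / 2)
    iso <- config$qtl_isolation %||% 1.2e5
    near <- genes |>
      inner_join(qtl_genes, by = "chrom", relationship = "many-to-many") |>
      filter(abs((.data$start + .data$end) / 2 - .data$mid) <= iso,
             .data$id != .data$gene)
    isolated_gene_ids <- unique(near$id)
  }

  plan <- config$mre_plan
  if (is.null(plan) && config$n_mirna >= 2 && nrow(lincs) >= 2 &&
      nrow(genes) >= 14) {
    host_pool <- genes |> filter(!.data$id %in% c(qtl_genes$gene,
                                                  isolated_gene_ids))
    if (nrow(host_pool) >= 14) {
      lnc_hosts <- sample(lincs$id, 2)
      gene_hosts <- sample(host_pool$id, 14)
      plan <- tibble(
        mirna = rep(1:2, times = c(8, 8)),
        host = c(lnc_hosts[1], gene_hosts[1:7], lnc_hosts[2],
                 gene_hosts[8:14]),
        mismatches = 0L,
        tissue = rep(c("leaf", "root"), times = c(8, 8)))
    }
  }

  # planted expression effects: plan hosts + QTL-linked genes + random rest
  de_override <- config$de_transcripts
  if (is.null(de_override)) {
    de <- tibble(transcript = character(0), tissue = character(0),
                 log2fc = numeric(0))
    if (!is.null(plan) && nrow(plan) > 0)
      # ceRNA plan members respond in both tissues so decoy and targets
      # share one expression pattern (the co-expression edge is real)
      de <- bind_rows(de, tibble(
        transcript = rep(plan$host, each = 2),
        tissue = rep(c("leaf", "root"), nrow(plan)),
        log2fc = config$log2fc_effect))
    if (nrow(qtl_genes) > 0)
      # QTL-linked genes emulate consistently LN-responsive candidates:
      # the planted effect acts in both tissues
      de <- bind_rows(de, tibble(
        transcript = rep(qtl_genes$gene, each = 2),
        tissue = rep(c("leaf", "root"), nrow(qtl_genes)),
        log2fc = config$log2fc_effect))
    n_extra <- max(0, floor(config$de_fraction * nrow(anno)) - nrow(de))
    if (n_extra > 0) {
      rest <- setdiff(anno$id, c(de$transcript, isolated_gene_ids))
      pick <- sample(rest, min(n_extra, length(rest)))
      de <- bind_rows(de, tibble(
        transcript = pick,
        tissue = sample(unique(config$design$tissue), length(pick),
                        replace = TRUE),
        log2fc = sample(c(-1, 1), length(pick), replace = TRUE) *
          config$log2fc_effect))
    }
    de <- de |> distinct(.data$transcript, .data$tissue, .keep_all = TRUE)
    config$de_transcripts <- de
  }
  if (!is.null(plan) && nrow(plan) > 0)
    config$precise_transcripts <- plan$host

  expr <- simulate_expression(ann, config)

  prec_hosts <- character(0)
  if (config$n_precursor_lncrnas > 0) {
    avail <- setdiff(lincs$id, if (!is.null(plan)) plan$host else character(0))
    prec_hosts <- head(avail, config$n_precursor_lncrnas)
  }
  mir <- simulate_mirna(config, ann$sequences, mre_plan = plan,
                        precursor_hosts = prec_hosts)

  geno <- simulate_genotypes(config)

  # resolve QTLs to the nearest sufficiently common marker per linked gene
  if (config$n_qtl > 0 && is.null(config$qtl_spec)) {
    st <- snp_stats(geno)
    qrows <- vector("list", nrow(qtl_genes))
    for (k in seq_len(nrow(qtl_genes))) {
      cand <- st |> filter(.data$chrom == qtl_genes$chrom[k],
                           .data$maf >= 0.2)
      if (nrow(cand) == 0) cand <- st |> filter(.data$maf >= 0.2)
      cand <- cand |> mutate(d = abs(.data$pos - qtl_genes$mid[k])) |>
        arrange(.data$d)
      qrows[[k]] <- tibble(snp = cand$snp[1], trait = config$qtl_trait,
                           ve = config$qtl_ve, treatment = "LN",
                           gene = qtl_genes$gene[k])
    }
    config$qtl_spec <- bind_rows(qrows)
  }
  phen <- simulate_phenotypes(geno, config)

  list(annotation = ann$annotation,
       sequences = mir$sequences,
       expression = expr$expression,
       mirna = mir,
       genotypes = geno,
       phenotypes = phen$phenotypes,
       config = config,
       truth = list(types = ann$truth,
                    de = expr$truth,
                    mre = mir$truth$mre,
                    precursor = mir$truth$precursor,
                    de_mirna = mir$truth$de_mirna,
                    qtl = phen$truth$qtl,
                    h2 = phen$truth$h2))
}
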