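# Shared fixture builders; everything is generated in code at test time.

one_tissue_design <- function(tissue = "leaf", n_reps = 3) {
  dplyr::filter(default_design(n_reps), .data$tissue == !!tissue)
}

# NB count matrix over a 3v3 one-tissue design with optional planted
# LN-specific fold changes.
nb_counts <- function(seed, n = 500, de_frac = 0, log2fc = 2,
                      dispersion = 0.1, base = NULL, tissue = "leaf") {
  set.seed(seed)
  des <- one_tissue_design(tissue)
  mu <- if (is.null(base)) stats::rlnorm(n, 4, 1.5) else rep(base, n)
  de <- sample(seq_len(n)) <= round(de_frac * n)
  cnt <- sapply(seq_len(nrow(des)), function(j) {
    m <- mu
    if (des$nitrogen[j] == "LN") m[de] <- m[de] * 2^log2fc
    stats::rnbinom(n, mu = m, size = 1 / dispersion)
  })
  rownames(cnt) <- paste0("t", seq_len(n))
  colnames(cnt) <- des$sample
  list(x = expression_matrix(cnt, des,
                             lengths = stats::setNames(rep(1000, n),
                                                       rownames(cnt))),
       de = de)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A transcript carrying an exact binding site for `mirna`.
host_with_site <- function(mirna, flank = 80) {
  paste0(random_dna_str(flank), revcomp(mirna), random_dna_str(flank))
}

# Brute-force exon-overlap test between two annotation rows.
overlaps_brute <- function(row1, row2, opposite_strand = FALSE) {
  if (row1$chrom != row2$chrom) return(FALSE)
  if (opposite_strand && row1$strand == row2$strand) return(FALSE)
  if (!opposite_strand && row1$strand != row2$strand) return(FALSE)
  e1 <- row1$exons[[1]]; e2 <- row2$exons[[1]]
  for (i in seq_len(nrow(e1))) for (j in seq_len(nrow(e2)))
    if (e1$start[i] <= e2$end[j] && e1$end[i] >= e2$start[j]) return(TRUE)
  FALSE
}

# Independent ungapped penalty oracle for the miRNA scanner.
penalty_oracle <- function(mirna, target) {
  L <- nchar(mirna)
  rc <- strsplit(revcomp(mirna), "")[[1]]
  tc <- strsplit(toupper(target), "")[[1]]
  if (length(tc) < L) return(Inf)
  w <- rev(ifelse(seq_len(L) %in% 2:13, 2, 1))
  best <- Inf
  for (o in seq_len(length(tc) - L + 1)) {
    pen <- 0
    for (s in seq_len(L)) {
      mb <- rc[s]; tb <- tc[o + s - 1]
      cost <- if (tb == mb) 0
      else if ((mb == "C" && tb == "T") || (mb == "A" && tb == "G")) 0.5
      else 1
      pen <- pen + cost * w[s]
    }
    best <- min(best, pen)
  }
  best
}

# Small line-trial phenotype table with known variance components.
pheno_fixture <- function(seed, n_lines = 50, reps = 3, s2g = 0.6,
                          s2e = 0.4, treatments = c("HN", "LN"),
                          trait = "SL", mu = c(HN = 10, LN = 8)) {
  set.seed(seed)
  lines <- sprintf("L%03d", seq_len(n_lines))
  g <- stats::rnorm(n_lines, 0, sqrt(s2g))
  dplyr::bind_rows(lapply(treatments, function(tr) {
    tibble::tibble(line = rep(lines, each = reps), treatment = tr,
                   replicate = rep(seq_len(reps), n_lines), trait = trait,
                   value = mu[[tr]] + rep(g, each = reps) +
                     stats::rnorm(n_lines * reps, 0, sqrt(s2e)))
  }))
}
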