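# Light S3 containers for the two matrix-shaped inputs. Everything derived
# from them is returned as a tibble.

#' Construct an expression matrix with sample design metadata
#'
#' Transcripts x samples abundance container. `design` maps every sample to
#' its tissue, nitrogen treatment and replicate; the twelve-sample default
#' study layout is 2 tissues x 2 nitrogen levels x 3 replicates.
#'
#' @param values Non-negative numeric matrix, rownames = transcript ids,
#'   colnames = sample ids.
#' @param design Data frame with columns `sample`, `tissue`, `nitrogen`,
#'   `replicate`; must cover every column of `values`.
#' @param lengths Optional named vector of effective transcript lengths (bp),
#'   required for [fpkm()]/[tpm()].
#' @param unit One of `"count"`, `"fpkm"`, `"tpm"`, `"normalized"`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, design, lengths = NULL, unit = "count") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("`values` needs transcript rownames and sample colnames")
  if (any(values < 0, na.rm = TRUE)) abort("negative abundance entries")
  design <- as_tibble(design)
  need <- c("sample", "tissue", "nitrogen", "replicate")
  if (!all(need %in% names(design)))
    abort("`design` must have columns sample, tissue, nitrogen, replicate")
  if (!all(colnames(values) %in% design$sample))
    abort("every sample must have a design entry")
  design <- design[match(colnames(values), design$sample), ]
  if (!is.null(lengths)) {
    if (!all(rownames(values) %in% names(lengths)))
      abort("`lengths` must cover every transcript")
    lengths <- lengths[rownames(values)]
    if (any(lengths <= 0)) abort("transcript lengths must be positive")
  }
  structure(list(values = values, design = design, lengths = lengths,
                 unit = unit, size_factors = NULL),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d transcripts x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$unit))
  if (!is.null(x$size_factors))
    cat("  size factors:", paste(signif(x$size_factors, 3), collapse = " "), "\n")
  print(utils::head(x$values[, seq_len(min(6, ncol(x$values))), drop = FALSE], 4))
  invisible(x)
}

#' Tidy an expression matrix into long form
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per (transcript, sample) carrying the design.
#' @export
#' @exportS3Method generics::tidy
tidy.expr_matrix <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "transcript") |>
    tidyr::pivot_longer(-"transcript", names_to = "sample",
                        values_to = "abundance")
  left_join(long, x$design, by = "sample")
}

#' Subset an expression matrix to a set of samples
#' @param x An `expr_matrix`.
#' @param samples Character vector of sample ids.
#' @return An `expr_matrix` restricted to those samples.
#' @export
select_samples <- function(x, samples) {
  stopifnot(inherits(x, "expr_matrix"), all(samples %in% colnames(x$values)))
  out <- x
  out$values <- x$values[, samples, drop = FALSE]
  out$design <- x$design[match(samples, x$design$sample), ]
  out
}

#' Construct a genotype matrix with a marker map
#'
#' Lines x SNPs dosage container; dosages are 0/1/2 minor-allele counts with
#' `NA` for missing calls.
#'
#' @param dosage Numeric matrix, rownames = line ids, colnames = SNP ids,
#'   entries in \{0, 1, 2, NA\}.
#' @param map Data frame with columns `snp`, `chrom`, `pos` (bp); positions
#'   must be sorted within chromosome.
#' @return An object of class `geno_matrix`.
#' @export
genotype_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    abort("`dosage` needs line rownames and SNP colnames")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) abort("dosages must be 0, 1, 2 or NA")
  map <- as_tibble(map)
  if (!all(c("snp", "chrom", "pos") %in% names(map)))
    abort("`map` must have columns snp, chrom, pos")
  if (!all(colnames(dosage) %in% map$snp))
    abort("every SNP column needs a map entry")
  map <- map[match(colnames(dosage), map$snp), ]
  srt <- map |> group_by(.data$chrom) |>
    summarise(sorted = !is.unsorted(.data$pos), .groups = "drop")
  if (!all(srt$sorted)) abort("map positions must be sorted within chromosome")
  structure(list(dosage = dosage, map = map, lines = rownames(dosage)),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d lines x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Per-SNP minor allele frequency and missingness
#'
#' @param geno A `geno_matrix`.
#' @return Tibble with columns `snp`, `chrom`, `pos`, `maf`, `missing`.
#' @export
snp_stats <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  p <- colMeans(geno$dosage, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(geno$dosage))
  geno$map |> mutate(maf = unname(maf), missing = unname(miss))
}

# Mean-impute missing dosages per SNP (columns with all-missing become the
# overall mean 0). Returns a plain matrix.
impute_dosage <- function(geno) {
  d <- geno$dosage
  if (!anyNA(d)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  d
}
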