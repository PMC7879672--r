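# Internal helpers shared across modules.

#' Derive a reproducible per-stage seed from a global seed
#'
#' Every simulator and every pipeline stage draws its randomness from a seed
#' fanned out from the single global seed by this documented hash, so stages
#' are independently reproducible. The result always fits in a 32-bit
#' integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"annotation"`).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(seed) %% 30000L * 69069 + h) %% 2147483647)
}

random_dna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", toupper(s)),
                       "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

seq_chars <- function(x) strsplit(toupper(x), "")[[1]]

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTNRYSWKMBDHU]", toupper(x))
  if (any(bad)) {
    abort(sprintf("malformed %s: non-IUPAC characters in %d entr%s",
                  what, sum(bad), if (sum(bad) == 1) "y" else "ies"))
  }
  invisible(x)
}

# Eigen-based matrix square root of a (possibly slightly indefinite)
# symmetric matrix; eigenvalues floored at `floor_at`.
psd_sqrt <- function(K, floor_at = 1e-8) {
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, floor_at)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Bend a symmetric matrix to positive semidefinite by eigenvalue flooring.
# Matrices that are already PSD (zero eigenvalues included) pass through
# unchanged, so exact-formula kinship stays exact.
bend_psd <- function(K, floor_at = 1e-6) {
  e <- eigen(K, symmetric = TRUE)
  # eigenvalues at numerical zero are fine (the mixed model clamps them);
  # only genuine indefiniteness is repaired
  if (min(e$values) >= -1e-8) return(K)
  vals <- pmax(e$values, floor_at)
  out <- e$vectors %*% (vals * t(e$vectors))
  dimnames(out) <- dimnames(K)
  (out + t(out)) / 2
}

# Row-standardize a matrix (mean 0, sd 1 per row); rows with zero variance
# come back as NA rows.
scale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  out <- (m - mu) / s
  out[s == 0, ] <- NA_real_
  out
}

# log2(x + 1) transform used for all expression correlations.
log2p1 <- function(m) log2(m + 1)
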