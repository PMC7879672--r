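# Mixed-linear-model association mapping: marker QC, VanRaden kinship,
# principal-component structure covariates, an EMMA-style REML fit of the
# null model with per-marker generalized least squares (the P3D
# approximation), and linkage-disequilibrium decay distance estimation.

#' Filter markers on minor allele frequency and missingness
#'
#' Retains SNPs with MAF at least `maf_min` and missing fraction at most
#' `missing_max` (a SNP with missing rate strictly above the cutoff is
#' removed); remaining missing dosages are mean-imputed per SNP for model
#' fitting, with the imputed cells flagged.
#'
#' @param geno A [genotype_matrix()].
#' @param maf_min MAF threshold (default 0.01).
#' @param missing_max Missing-rate threshold (default 0.2).
#' @return A `geno_matrix` of surviving, imputed SNPs; attributes
#'   `"imputed"` (logical matrix of imputed cells) and `"removed"`
#'   (dropped SNP ids).
#' @export
filter_markers <- function(geno, maf_min = 0.01, missing_max = 0.2) {
  stopifnot(inherits(geno, "geno_matrix"))
  st <- snp_stats(geno)
  keep <- !is.na(st$maf) & st$maf >= maf_min & st$missing <= missing_max
  if (!any(keep)) abort("over-filtering: no SNP survives")
  d <- geno$dosage[, keep, drop = FALSE]
  imp <- is.na(d)
  if (any(imp)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(imp, arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  out <- structure(list(dosage = d, map = geno$map[keep, ],
                        lines = geno$lines), class = "geno_matrix")
  attr(out, "imputed") <- imp
  attr(out, "removed") <- st$snp[!keep]
  out
}

#' VanRaden genomic relationship (kinship) matrix
#'
#' `K = W W' / (2 * sum p_k (1 - p_k))` with `W` the dosage matrix centred
#' at twice the allele frequency; bent to positive semidefinite by
#' eigenvalue flooring at 1e-6 when needed.
#'
#' @param geno A (filtered) [genotype_matrix()]; missing dosages are
#'   mean-imputed.
#' @return Symmetric lines x lines matrix of class `matrix`.
#' @export
kinship <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- impute_dosage(geno)
  p <- colMeans(d) / 2
  W <- sweep(d, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("no polymorphic SNPs for kinship")
  K <- tcrossprod(W) / denom
  bend_psd(K)
}

#' Principal-component structure covariates
#'
#' Top `k` principal components of the centred dosage matrix, standing in
#' for the population-structure matrix (the panel's reported structure has
#' K = 2 groups, hence the default). Deterministic sign convention: the
#' loading of largest magnitude on each component is positive.
#'
#' @param geno A (filtered) [genotype_matrix()].
#' @param k Number of components (default 2; 0 gives a 0-column matrix).
#' @return Numeric matrix, lines x k, columns `PC1..PCk`.
#' @export
structure_covariates <- function(geno, k = 2) {
  stopifnot(inherits(geno, "geno_matrix"))
  n <- nrow(geno$dosage)
  if (k >= n) abort("invalid k: need k < number of lines")
  if (k == 0)
    return(matrix(0, n, 0, dimnames = list(geno$lines, NULL)))
  d <- impute_dosage(geno)
  pc <- prcomp(d, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(geno$lines, paste0("PC", seq_len(k)))
  scores
}

# REML log-likelihood of the null model on the kinship eigenbasis,
# profiled over delta = sigma2_e / sigma2_g.
.reml_ll <- function(log_delta, d, ystar, Xstar) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  A <- Xstar * sw
  b <- ystar * sw
  qra <- qr(A)
  res <- qr.resid(qra, b)
  rss <- sum(res^2)
  n <- length(ystar); p <- ncol(Xstar)
  s2 <- rss / (n - p)
  ldetXWX <- 2 * sum(log(abs(diag(qr.R(qra)))))
  -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(d + delta)) + ldetXWX)
}

#' Mixed-linear-model association scan
#'
#' Fits `y = X beta + u + e`, `u ~ N(0, K sigma2_g)`, estimating the
#' variance components once on the null model by REML profiled over
#' `delta = sigma2_e / sigma2_g` on the eigendecomposition of the kinship
#' matrix (the P3D approximation), then testing each marker by generalized
#' least squares with a two-sided Wald test (t reference, `n - p - 1`
#' degrees of freedom, which reduces exactly to the ordinary F test when
#' `K` is the identity). Marker R2 is the incremental variance explained on
#' the GLS-whitened scale, in percent.
#'
#' @param geno A filtered [genotype_matrix()].
#' @param phenotype Named numeric vector of line phenotypes (names matched
#'   to line ids; an unnamed vector must follow `geno$lines` order).
#' @param K Kinship matrix (default [kinship()] of `geno`).
#' @param covariates Optional lines x q covariate matrix (e.g.
#'   [structure_covariates()]); collinear columns are dropped with a
#'   warning.
#' @param p_threshold Significance threshold (default `10^-4.6`).
#' @return Object of class `mlm_scan`: list with `results` tibble (`snp`,
#'   `chrom`, `pos`, `beta`, `se`, `stat`, `p_value`, `r2_pct`,
#'   `significant`), variance components `sigma2_g`, `sigma2_e`, `delta`,
#'   and fit metadata. Use [tidy()]/[glance()]/[autoplot()].
#' @export
mlm_scan <- function(geno, phenotype, K = NULL, covariates = NULL,
                     p_threshold = 10^-4.6) {
  stopifnot(inherits(geno, "geno_matrix"))
  n <- nrow(geno$dosage)
  y <- phenotype
  if (!is.null(names(y))) {
    if (!all(geno$lines %in% names(y)))
      abort("phenotype must cover every genotyped line")
    y <- y[geno$lines]
  } else if (length(y) != n) abort("phenotype length must match lines")
  if (anyNA(y)) abort("phenotype contains missing values")
  K <- K %||% kinship(geno)
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (!is.null(rownames(cv))) cv <- cv[geno$lines, , drop = FALSE]
    X0 <- cbind(X0, cv)
  }
  qx <- qr(X0)
  if (qx$rank < ncol(X0)) {
    warn("dropping collinear covariates")
    X0 <- X0[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  p0 <- ncol(X0)

  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-4) abort("numeric failure: kinship not PSD")
  U <- eg$vectors
  ystar <- crossprod(U, y)[, 1]
  X0s <- crossprod(U, X0)

  opt <- optimize(function(ld) .reml_ll(ld, d, ystar, X0s),
                  interval = c(-10, 10), maximum = TRUE)
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  A <- X0s * sw
  b <- ystar * sw
  qra <- qr(A)
  res0 <- qr.resid(qra, b)
  rss0 <- sum(res0^2)
  sigma2_g <- rss0 / (n - p0)
  sigma2_e <- delta * sigma2_g

  G <- crossprod(U, impute_dosage(geno)) * sw   # whitened markers
  Gres <- qr.resid(qra, G)
  xx <- colSums(Gres^2)
  xy <- as.vector(crossprod(Gres, res0))
  ok <- xx > 1e-10
  beta <- ifelse(ok, xy / xx, 0)
  rss1 <- pmax(rss0 - ifelse(ok, xy^2 / xx, 0), 0)
  df <- n - p0 - 1
  s2 <- rss1 / df
  se <- ifelse(ok, sqrt(s2 / xx), NA_real_)
  tstat <- ifelse(ok, beta / se, 0)
  p <- ifelse(ok, 2 * pt(-abs(tstat), df), 1)
  r2 <- ifelse(ok, 100 * (rss0 - rss1) / rss0, 0)

  results <- geno$map |>
    mutate(beta = beta, se = se, stat = tstat, p_value = p,
           r2_pct = r2, significant = p < p_threshold)
  structure(list(results = results, sigma2_g = sigma2_g,
                 sigma2_e = sigma2_e, delta = delta, n_lines = n,
                 n_snps = ncol(geno$dosage), p_threshold = p_threshold,
                 df = df, reml_ll = opt$objective),
            class = "mlm_scan")
}

#' @export
print.mlm_scan <- function(x, ...) {
  cat(sprintf(paste0("<mlm_scan> %d lines x %d SNPs | sigma2_g %.3g, ",
                     "sigma2_e %.3g | %d significant at p < %.2g\n"),
              x$n_lines, x$n_snps, x$sigma2_g, x$sigma2_e,
              sum(x$results$significant), x$p_threshold))
  invisible(x)
}

#' @rdname mlm_scan
#' @param x,object An `mlm_scan`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.mlm_scan <- function(x, ...) x$results

#' @rdname mlm_scan
#' @export
#' @exportS3Method generics::glance
glance.mlm_scan <- function(x, ...) {
  tibble(sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e, delta = x$delta,
         heritability_mlm = x$sigma2_g / (x$sigma2_g + x$sigma2_e),
         n_lines = x$n_lines, n_snps = x$n_snps,
         n_significant = sum(x$results$significant),
         p_threshold = x$p_threshold)
}

#' Manhattan plot of an association scan
#' @rdname mlm_scan
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.mlm_scan <- function(object, ...) {
  res <- object$results |>
    group_by(.data$chrom) |> mutate(pos_mb = .data$pos / 1e6) |> ungroup()
  ggplot2::ggplot(res, ggplot2::aes(.data$pos_mb, -log10(.data$p_value),
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(object$p_threshold),
                        linetype = "dashed") +
    ggplot2::facet_grid(~ .data$chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' Linkage-disequilibrium decay distance
#'
#' Pairwise r2 (squared Pearson correlation of dosages) for
#' intra-chromosome marker pairs within `max_dist`, averaged in distance
#' bins and smoothed by local regression; the decay distance is the
#' smallest distance at which the smoothed r2 falls below `r2_threshold`,
#' and the genome average is the mean over chromosomes.
#'
#' @param geno A [genotype_matrix()] (missing dosages mean-imputed).
#' @param max_dist Maximum pair distance in bp (default: half the largest
#'   intra-chromosome span).
#' @param r2_threshold Decay threshold (default 0.1).
#' @param n_bins Number of distance bins (default 50).
#' @return Object of class `ld_decay`: `curve` (binned + smoothed r2),
#'   `per_chrom` decay distances, `average` (bp).
#' @export
ld_decay <- function(geno, max_dist = NULL, r2_threshold = 0.1,
                     n_bins = 50) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- impute_dosage(geno)
  chroms <- unique(geno$map$chrom)
  if (is.null(max_dist)) {
    spans <- geno$map |> group_by(.data$chrom) |>
      summarise(s = diff(range(.data$pos)), .groups = "drop")
    max_dist <- max(spans$s) / 2
  }
  pair_rows <- list()
  for (ch in chroms) {
    idx <- which(geno$map$chrom == ch)
    if (length(idx) < 2) abort("need at least two SNPs per chromosome")
    pos <- geno$map$pos[idx]
    Z <- d[, idx, drop = FALSE]
    v <- apply(Z, 2, var)
    poly <- v > 0
    Z <- Z[, poly, drop = FALSE]; pos <- pos[poly]
    if (ncol(Z) < 2) next
    R <- cor(Z)
    m <- length(pos)
    ii <- rep(seq_len(m - 1), times = (m - 1):1)
    jj <- sequence((m - 1):1) + ii
    dist <- pos[jj] - pos[ii]
    keep <- dist <= max_dist
    if (!any(keep)) abort("insufficient marker density within max_dist")
    pair_rows[[ch]] <- tibble(chrom = ch, dist = dist[keep],
                              r2 = R[cbind(ii[keep], jj[keep])]^2)
  }
  pairs <- bind_rows(pair_rows)
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  curve_all <- pairs |>
    mutate(bin = cut(.data$dist, breaks, labels = FALSE,
                     include.lowest = TRUE)) |>
    group_by(.data$chrom, .data$bin) |>
    summarise(mean_r2 = mean(.data$r2), n_pairs = n(), .groups = "drop") |>
    mutate(dist = mids[.data$bin])
  decay_one <- function(cv) {
    if (nrow(cv) < 4) return(NA_real_)
    sm <- loess(mean_r2 ~ dist, data = cv, span = 0.5,
                weights = cv$n_pairs)
    cv$smooth_r2 <- predict(sm, cv$dist)
    below <- which(cv$smooth_r2 < r2_threshold)
    if (!length(below)) return(NA_real_)
    cv$dist[min(below)]
  }
  per_chrom <- curve_all |> group_by(.data$chrom) |>
    group_modify(~ tibble(decay = decay_one(.x))) |> ungroup()
  smooth_curves <- curve_all |> group_by(.data$chrom) |>
    group_modify(function(cv, key) {
      if (nrow(cv) >= 4) {
        sm <- loess(mean_r2 ~ dist, data = cv, span = 0.5,
                    weights = cv$n_pairs)
        cv$smooth_r2 <- predict(sm, cv$dist)
      } else cv$smooth_r2 <- cv$mean_r2
      cv
    }) |> ungroup()
  avg <- mean(per_chrom$decay, na.rm = TRUE)
  if (is.nan(avg)) {
    warn("no chromosome reached the r2 threshold within max_dist")
    avg <- NA_real_
  }
  structure(list(curve = smooth_curves, per_chrom = per_chrom,
                 average = avg, r2_threshold = r2_threshold,
                 max_dist = max_dist),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("<ld_decay> average decay distance %.0f bp (r2 < %.2g)\n",
              x$average, x$r2_threshold))
  invisible(x)
}

#' @rdname ld_decay
#' @param x,object An `ld_decay`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.ld_decay <- function(x, ...) x$curve

#' @rdname ld_decay
#' @export
#' @exportS3Method generics::glance
glance.ld_decay <- function(x, ...) {
  tibble(average_decay = x$average, r2_threshold = x$r2_threshold,
         max_dist = x$max_dist,
         n_chrom = nrow(x$per_chrom))
}

#' @rdname ld_decay
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ld_decay <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$dist / 1e3, .data$mean_r2,
                               colour = .data$chrom)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth_r2)) +
    ggplot2::geom_hline(yintercept = object$r2_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "distance (kb)", y = expression(r^2)) +
    ggplot2::theme_minimal()
}
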