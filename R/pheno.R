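# Phenotype statistics for replicated line trials under two nitrogen
# treatments: descriptive summaries, two-way ANOVA F values, broad-sense
# heritability from the one-way random-effects model, trait correlations,
# and the low-nitrogen tolerance index (LNTI) feeding GWAS.

.check_pheno <- function(table) {
  need <- c("line", "treatment", "replicate", "trait", "value")
  if (!all(need %in% names(table)))
    abort("phenotype table needs columns line, treatment, replicate, trait, value")
  if (any(!is.finite(table$value))) abort("phenotype values must be finite")
  invisible(table)
}

# Fisher g1 skewness and g2 excess kurtosis; degenerate vectors -> 0.
.moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(c(skew = 0, kurtosis = 0, degenerate = 1))
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3
  c(skew = g1, kurtosis = g2, degenerate = 0)
}

#' Broad-sense heritability of line means
#'
#' One-way random-effects ANOVA over lines within a treatment:
#' `sigma2_G = (MS_G - MS_e) / r` with `r` the harmonic-mean replicate
#' count, `sigma2_e = MS_e`, and
#' `H2 = sigma2_G / (sigma2_G + sigma2_e / r)`, truncated to \[0, 1\].
#'
#' @param table Long phenotype tibble (`line`, `treatment`, `replicate`,
#'   `trait`, `value`).
#' @param trait,treatment Which trait/treatment to analyse.
#' @return One-row tibble: `trait`, `treatment`, `H2`, `sigma2_G`,
#'   `sigma2_e`, `r_harmonic`, `degenerate`.
#' @export
heritability <- function(table, trait, treatment) {
  .check_pheno(table)
  d <- table |> filter(.data$trait == !!trait, .data$treatment == !!treatment)
  reps <- d |> count(.data$line)
  if (nrow(reps) < 2 || any(reps$n < 2))
    abort("need at least two lines with two replicates each")
  r_h <- nrow(reps) / sum(1 / reps$n)
  fit <- anova(lm(value ~ factor(line), data = d))
  ms_g <- fit$`Mean Sq`[1]
  ms_e <- fit$`Mean Sq`[2]
  if (var(tapply(d$value, d$line, mean)) == 0) {
    return(tibble(trait = trait, treatment = treatment, H2 = 0,
                  sigma2_G = 0, sigma2_e = ms_e, r_harmonic = r_h,
                  degenerate = TRUE))
  }
  s2g <- (ms_g - ms_e) / r_h
  h2 <- s2g / (s2g + ms_e / r_h)
  tibble(trait = trait, treatment = treatment,
         H2 = min(1, max(0, h2)), sigma2_G = s2g, sigma2_e = ms_e,
         r_harmonic = r_h, degenerate = FALSE)
}

#' Two-way ANOVA F values for treatment and genotype
#'
#' Sequential (type-I) sums of squares in the listed factor order
#' (treatment, then genotype) on replicate-level data, F ratios against the
#' residual mean square. With `per_treatment = TRUE`, a one-way genotype
#' ANOVA is additionally run within each treatment.
#'
#' @param table Long phenotype tibble.
#' @param trait Trait to analyse.
#' @param per_treatment Also return within-treatment genotype F values.
#' @return Tibble: `trait`, `scope`, `F_treatment`, `F_genotype`,
#'   `p_treatment`, `p_genotype`.
#' @export
anova_f <- function(table, trait, per_treatment = FALSE) {
  .check_pheno(table)
  d <- table |> filter(.data$trait == !!trait)
  if (length(unique(d$treatment)) < 2 || length(unique(d$line)) < 2)
    abort("both factors need at least two levels")
  fit <- anova(lm(value ~ factor(treatment) + factor(line), data = d))
  out <- tibble(trait = trait, scope = "pooled",
                F_treatment = fit$`F value`[1],
                F_genotype = fit$`F value`[2],
                p_treatment = fit$`Pr(>F)`[1],
                p_genotype = fit$`Pr(>F)`[2])
  if (per_treatment) {
    extra <- d |> group_by(.data$treatment) |> group_modify(function(g, key) {
      f <- anova(lm(value ~ factor(line), data = g))
      tibble(trait = trait, F_treatment = NA_real_,
             F_genotype = f$`F value`[1], p_treatment = NA_real_,
             p_genotype = f$`Pr(>F)`[1])
    }) |> ungroup() |> mutate(scope = .data$treatment) |>
      select("trait", "scope", "F_treatment", "F_genotype",
             "p_treatment", "p_genotype")
    out <- bind_rows(out, extra)
  }
  out
}

#' Table-2-style trait summary
#'
#' Per (trait, treatment): mean, sd (n-1), min, max, Fisher g1 skewness and
#' g2 excess kurtosis (0 with a flag for degenerate vectors), broad-sense
#' heritability, and the pooled two-way ANOVA F values for treatment and
#' genotype.
#'
#' @param table Long phenotype tibble.
#' @return Tibble with one row per (trait, treatment).
#' @export
summarize_traits <- function(table) {
  .check_pheno(table)
  desc <- table |> group_by(.data$trait, .data$treatment) |>
    summarise(n = n(), mean = mean(.data$value), sd = sd(.data$value),
              min = min(.data$value), max = max(.data$value),
              skew = .moments(.data$value)[["skew"]],
              kurtosis = .moments(.data$value)[["kurtosis"]],
              degenerate = .moments(.data$value)[["degenerate"]] == 1,
              .groups = "drop")
  if (any(desc$n < 2)) abort("insufficient data: fewer than two observations")
  h2 <- desc |> select("trait", "treatment") |>
    pmap(function(trait, treatment)
      heritability(table, trait, treatment)) |>
    bind_rows() |> select("trait", "treatment", "H2")
  two_way_ok <- length(unique(table$treatment)) >= 2 &&
    length(unique(table$line)) >= 2
  fv <- if (two_way_ok) {
    unique(desc$trait) |>
      map(function(tr) anova_f(table, tr)) |> bind_rows() |>
      select("trait", "F_treatment", "F_genotype")
  } else {
    tibble(trait = unique(desc$trait), F_treatment = NA_real_,
           F_genotype = NA_real_)
  }
  desc |> left_join(h2, by = c("trait", "treatment")) |>
    left_join(fv, by = "trait") |>
    arrange(match(.data$trait, unique(table$trait)), .data$treatment)
}

#' Low-nitrogen tolerance index
#'
#' Per line and trait, the mean trait value under HN divided by the mean
#' value under LN (`invert = TRUE` gives LN/HN). Lines with an LN mean of
#' zero are excluded with a flag.
#'
#' @param table Long phenotype tibble.
#' @param traits Traits to index (default: all present).
#' @param invert Report LN/HN instead of HN/LN.
#' @return Tibble: `line`, `trait`, `lnti`, `excluded`.
#' @export
lnti <- function(table, traits = NULL, invert = FALSE) {
  .check_pheno(table)
  traits <- traits %||% unique(table$trait)
  wide <- table |> filter(.data$trait %in% traits) |>
    group_by(.data$line, .data$trait, .data$treatment) |>
    summarise(m = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "m")
  if (!all(c("HN", "LN") %in% names(wide)))
    abort("both HN and LN means required for LNTI")
  den <- if (invert) wide$HN else wide$LN
  num <- if (invert) wide$LN else wide$HN
  wide |> mutate(lnti = ifelse(den == 0, NA_real_, num / den),
                 excluded = den == 0) |>
    select("line", "trait", "lnti", "excluded")
}

#' Pairwise Pearson correlations between traits
#'
#' Computed on per-line means within a treatment; zero-variance traits are
#' excluded with a flag (the `"excluded"` attribute).
#'
#' @param table Long phenotype tibble.
#' @param treatment Which treatment's line means to correlate.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(table, treatment) {
  .check_pheno(table)
  d <- table |> filter(.data$treatment == !!treatment) |>
    group_by(.data$line, .data$trait) |>
    summarise(m = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "m")
  if (nrow(d) < 3) abort("need at least three lines")
  m <- as.matrix(d[, -1])
  vars <- apply(m, 2, var)
  excluded <- colnames(m)[vars == 0]
  m <- m[, vars > 0, drop = FALSE]
  out <- cor(m)
  attr(out, "excluded") <- excluded
  out
}
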