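test_that("descriptive moments behave at degenerate, symmetric and Gaussian inputs", {
  # constant vector: sd 0, skew/kurtosis reported 0 with flag
  ph <- tibble::tibble(line = rep(c("A", "B"), each = 3), treatment = "HN",
                       replicate = rep(1:3, 2), trait = "T", value = 5)
  s <- suppressWarnings(summarize_traits(ph))  # perfect-fit lm warning
  expect_equal(s$sd, 0)
  expect_equal(s$skew, 0)
  expect_true(s$degenerate)
  # symmetric vector has zero skewness
  m <- nitrolnc:::.moments(c(1, 2, 3))
  expect_equal(m[["skew"]], 0)
  # large-sample standard normal: skew ~ 0, excess kurtosis ~ 0
  set.seed(31)
  mg <- nitrolnc:::.moments(stats::rnorm(10000))
  expect_lt(abs(mg[["skew"]]), 0.05)
  expect_lt(abs(mg[["kurtosis"]]), 0.1)
})

test_that("heritability matches its closed form and limiting cases", {
  # zero residual variance with differing line means -> H2 = 1
  ph1 <- tibble::tibble(line = rep(c("A", "B", "C"), each = 3),
                        treatment = "LN", replicate = rep(1:3, 3),
                        trait = "T", value = rep(c(1, 5, 9), each = 3))
  expect_equal(suppressWarnings(heritability(ph1, "T", "LN"))$H2, 1)
  # identical lines with noisy replicates -> H2 near 0 on average
  h0 <- vapply(1:5, function(s)
    heritability(pheno_fixture(s + 30, n_lines = 100, s2g = 0, s2e = 1,
                               treatments = "LN"), "SL", "LN")$H2,
    numeric(1))
  expect_lt(mean(h0), 0.1)
  # closed-form recovery: s2g 0.6, s2e 0.4, 3 reps -> 0.818
  h2 <- vapply(1:20, function(s)
    heritability(pheno_fixture(s, n_lines = 250, treatments = "LN"),
                 "SL", "LN")$H2, numeric(1))
  expect_lt(abs(mean(h2) - 0.6 / (0.6 + 0.4 / 3)), 0.05)
  expect_error(heritability(ph1[1:3, ], "T", "LN"), "two lines")
})

test_that("two-way ANOVA F values match hand-computed expected mean squares", {
  # balanced 2 treatments x 2 lines x 2 reps toy table
  ph <- tidyr::expand_grid(treatment = c("HN", "LN"), line = c("A", "B"),
                           replicate = 1:2) |>
    dplyr::mutate(trait = "T",
                  value = c(10, 12, 14, 16, 20, 22, 24, 26))
  f <- anova_f(ph, "T")
  # hand arithmetic: SS_treatment = 8*(mean diff/2)^2 ...
  gm <- mean(ph$value)
  ss_t <- sum(tapply(ph$value, ph$treatment, function(v) 4 * (mean(v) - gm)^2))
  ss_g <- sum(tapply(ph$value, ph$line, function(v) 4 * (mean(v) - gm)^2))
  cellm <- with(ph, ave(value, treatment, line))
  ss_e <- sum((ph$value - cellm)^2)
  ms_e <- ss_e / (8 - 1 - 1 - 1)
  expect_equal(f$F_treatment, (ss_t / 1) / ms_e)
  expect_equal(f$F_genotype, (ss_g / 1) / ms_e)
  # factor isolation: pure treatment shift gives F_genotype near 1
  set.seed(33)
  big <- pheno_fixture(33, n_lines = 80, s2g = 0, s2e = 1)
  fb <- anova_f(big, "SL")
  expect_gt(fb$F_treatment, 50)   # mu HN 10 vs LN 8 on sd-1 noise
  expect_lt(fb$F_genotype, 2)
  expect_error(anova_f(dplyr::filter(big, treatment == "HN"), "SL"),
               "two levels")
})

test_that("treatment-null simulation gives calibrated treatment F p-values", {
  set.seed(34)
  ps <- vapply(1:40, function(s) {
    ph <- pheno_fixture(s + 500, n_lines = 20, s2g = 0.3, s2e = 1,
                        mu = c(HN = 10, LN = 10))
    anova_f(ph, "SL")$p_treatment
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("LNTI is the HN/LN ratio of line means with exclusions flagged", {
  ph <- tibble::tibble(line = rep(c("A", "B", "C"), each = 4),
                       treatment = rep(c("HN", "HN", "LN", "LN"), 3),
                       replicate = rep(c(1, 2, 1, 2), 3), trait = "T",
                       value = c(4, 6, 4, 6,   8, 12, 4, 6,   3, 5, 0, 0))
  idx <- lnti(ph)
  expect_equal(idx$lnti[idx$line == "A"], 1)   # HN = LN
  expect_equal(idx$lnti[idx$line == "B"], 2)   # HN = 2 LN
  expect_true(idx$excluded[idx$line == "C"])   # LN mean zero
  inv <- lnti(ph, invert = TRUE)
  expect_equal(inv$lnti[inv$line == "B"], 0.5)
})

test_that("trait correlations are symmetric with unit diagonal and exclusions", {
  set.seed(35)
  ph <- dplyr::bind_rows(lapply(c("SL", "COPY", "FLAT", "IND"), function(tr) {
    v <- if (tr == "FLAT") rep(1, 90) else stats::rnorm(90)
    tibble::tibble(line = rep(sprintf("L%02d", 1:30), each = 3),
                   treatment = "LN", replicate = rep(1:3, 30), trait = tr,
                   value = v)
  }))
  # make COPY a duplicate of SL
  sl <- dplyr::filter(ph, trait == "SL")
  ph$value[ph$trait == "COPY"] <- sl$value
  cm <- trait_correlations(ph, "LN")
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_equal(cm["SL", "COPY"], 1)
  expect_true("FLAT" %in% attr(cm, "excluded"))
  expect_lt(abs(cm["SL", "IND"]), 2 / sqrt(30) * 2)
})

test_that("summary statistics are invariant to trait rescaling", {
  ph <- pheno_fixture(36, n_lines = 40)
  ph2 <- dplyr::mutate(ph, value = value * 7.3)
  s1 <- summarize_traits(ph); s2 <- summarize_traits(ph2)
  expect_equal(s2$H2, s1$H2, tolerance = 1e-10)
  expect_equal(s2$F_treatment, s1$F_treatment, tolerance = 1e-10)
  expect_equal(s2$skew, s1$skew, tolerance = 1e-10)
  expect_equal(s2$kurtosis, s1$kurtosis, tolerance = 1e-10)
  expect_equal(lnti(ph2)$lnti, lnti(ph)$lnti, tolerance = 1e-12)
})
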