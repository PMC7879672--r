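make_feature_tbl <- function(ids, chrom, start, end, strand = "+") {
  tibble::tibble(id = ids, chrom = chrom, strand = strand,
                 start = start, end = end)
}

random_expr_for <- function(ids, seed = 1) {
  set.seed(seed)
  des <- default_design()
  v <- matrix(stats::rlnorm(length(ids) * 12, 3, 1), length(ids), 12,
              dimnames = list(ids, des$sample))
  expression_matrix(v, des, unit = "fpkm")
}

test_that("cis pairing honours the closed window boundary and chromosomes", {
  lnc <- make_feature_tbl("L1", "chr1", 1000, 2000)
  genes <- make_feature_tbl(c("Gexact", "Gbeyond", "Gother"),
                            c("chr1", "chr1", "chr2"),
                            c(2000 + 1e5, 2000 + 1e5 + 1, 2000 + 10),
                            c(2000 + 1e5 + 500, 2000 + 1e5 + 600,
                              2000 + 400))
  x <- random_expr_for(c("L1", genes$id))
  p <- find_cis_pairs(lnc, genes, x, window = 1e5)
  # gene starting exactly window bp from the lncRNA end is included
  expect_true("Gexact" %in% p$gene)
  expect_false("Gbeyond" %in% p$gene)
  expect_false("Gother" %in% p$gene)  # other chromosome is never cis
  expect_equal(p$distance[p$gene == "Gexact"], 1e5)
  # overlapping gene has distance 0
  g0 <- make_feature_tbl("Gov", "chr1", 1500, 1800)
  x0 <- random_expr_for(c("L1", "Gov"))
  p0 <- find_cis_pairs(lnc, g0, x0)
  expect_equal(p0$distance, 0)
  expect_equal(p0$side, "overlapping")
})

test_that("cis pair set equals the brute-force distance scan and is window-monotone", {
  set.seed(11)
  n <- 100
  feats <- make_feature_tbl(paste0("F", 1:n),
                            sample(paste0("chr", 1:3), n, TRUE),
                            s <- sample.int(5e5, n), s + 500)
  lnc <- feats[1:40, ]; genes <- feats[41:n, ]
  x <- random_expr_for(feats$id)
  got <- find_cis_pairs(lnc, genes, x, window = 1e5)
  # O(n^2) oracle
  oracle <- list()
  for (i in seq_len(nrow(lnc))) for (j in seq_len(nrow(genes))) {
    if (lnc$chrom[i] != genes$chrom[j]) next
    ov <- genes$start[j] <= lnc$end[i] && genes$end[j] >= lnc$start[i]
    d <- if (ov) 0 else max(genes$start[j] - lnc$end[i],
                            lnc$start[i] - genes$end[j])
    if (d <= 1e5) oracle[[length(oracle) + 1]] <-
        paste(lnc$id[i], genes$id[j], d)
  }
  expect_setequal(paste(got$lncrna, got$gene, got$distance),
                  unlist(oracle))
  # widening the window never removes a pair
  wide <- find_cis_pairs(lnc, genes, x, window = 2e5)
  expect_true(all(paste(got$lncrna, got$gene) %in%
                    paste(wide$lncrna, wide$gene)))
})

test_that("trans pairing applies the strict correlation threshold", {
  des <- default_design()
  base <- stats::rlnorm(12, 3, 1)
  v <- rbind(L1 = base, Gdouble = 2 * base, Ganti = max(base) - base + 1,
             Gflat = rep(5, 12),
             Gnoise = stats::rlnorm(12, 3, 1))
  colnames(v) <- des$sample
  x <- expression_matrix(v, des, unit = "fpkm")
  p <- find_trans_pairs("L1", c("Gdouble", "Ganti", "Gflat", "Gnoise"), x,
                        r_min = 0.95)
  expect_true("Gdouble" %in% p$gene)   # r = 1 on the log scale? see below
  expect_false("Ganti" %in% p$gene)    # negative correlation excluded
  expect_true("Gflat" %in% attr(p, "excluded"))
  # r computed on log2(x + 1): doubling gives r extremely close to 1
  expect_gt(p$pearson_r[p$gene == "Gdouble"], 0.99)
})

test_that("trans pair set matches the all-pairs correlation oracle", {
  set.seed(12)
  ids <- paste0("T", 1:50)
  x <- random_expr_for(ids, seed = 12)
  lncs <- ids[1:20]; genes <- ids[21:50]
  got <- find_trans_pairs(lncs, genes, x, r_min = 0.5)
  lv <- log2(x$values + 1)
  oracle <- list()
  for (a in lncs) for (b in genes) {
    r <- cor(lv[a, ], lv[b, ])
    if (!is.na(r) && r > 0.5)
      oracle[[length(oracle) + 1]] <- paste(a, b, round(r, 10))
  }
  expect_setequal(paste(got$lncrna, got$gene, round(got$pearson_r, 10)),
                  unlist(oracle))
})

test_that("site scanner reproduces hand-computed penalties and the identity case", {
  set.seed(13)
  m <- c(miR = random_dna_str(21))
  site <- revcomp(m)
  tgt <- c(t1 = paste0(strrep("C", 40), site, strrep("C", 40)))
  r <- scan_mirna_targets(m, tgt, max_penalty = 0, allow_bulge = FALSE)
  expect_equal(nrow(r), 1)
  expect_equal(r$penalty, 0)
  expect_equal(r$start, 41L)
  expect_equal(r$cleavage, 41L + 21L - 10L)  # opposite miRNA position 10
  expect_equal(r$alignment, strrep("|", 21))
  # single mismatch at miRNA position 5 -> 2.0; at position 20 -> 1.0
  mut <- function(p) {
    s <- site; sp <- 21 - p + 1
    b <- substr(s, sp, sp); mb <- substr(m, p, p)
    wob <- switch(mb, G = "T", T = "G", NA_character_)
    substr(s, sp, sp) <- setdiff(c("A", "C", "G", "T"), c(b, wob))[1]
    c(t = paste0(strrep("C", 30), s, strrep("C", 30)))
  }
  r5 <- scan_mirna_targets(m, mut(5), max_penalty = 5, allow_bulge = FALSE)
  r20 <- scan_mirna_targets(m, mut(20), max_penalty = 5, allow_bulge = FALSE)
  expect_equal(min(r5$penalty), 2)
  expect_equal(min(r20$penalty), 1)
  expect_error(scan_mirna_targets(c(x = "ACGT"), tgt), "18-26")
})

test_that("best-site penalties equal the exhaustive per-offset oracle", {
  set.seed(14)
  m <- c(miR = random_dna_str(21))
  for (i in 1:25) {
    tg <- c(t = random_dna_str(250))
    got <- scan_mirna_targets(m, tg, max_penalty = Inf,
                              allow_bulge = FALSE, best_only = TRUE)
    expect_equal(got$penalty, penalty_oracle(m[[1]], tg[[1]]))
  }
})

test_that("bulge scoring matches a brute-force bulged alignment oracle", {
  set.seed(15)
  m <- c(miR = random_dna_str(21))
  bulge_oracle <- function(mir, tgt) {
    L <- nchar(mir)
    rc <- strsplit(revcomp(mir), "")[[1]]
    tc <- strsplit(tgt, "")[[1]]
    w <- rev(ifelse(seq_len(L) %in% 2:13, 2, 1))
    bw <- 2 * ifelse((L - seq_len(L - 1)) %in% 2:13, 2, 1)
    cost1 <- function(mb, tb) {
      if (tb == mb) 0
      else if ((mb == "C" && tb == "T") || (mb == "A" && tb == "G")) 0.5
      else 1
    }
    best <- Inf
    for (o in seq_len(length(tc) - L)) {
      for (b in seq_len(L - 1)) {        # bulged base after site position b
        pen <- bw[b]
        tpos <- o
        for (s in seq_len(L)) {
          pen <- pen + cost1(rc[s], tc[tpos]) * w[s]
          tpos <- tpos + 1 + (s == b)
        }
        best <- min(best, pen)
      }
    }
    for (o in seq_len(length(tc) - L + 1)) {  # ungapped alternative
      pen <- sum(vapply(seq_len(L), function(s)
        cost1(rc[s], tc[o + s - 1]) * w[s], numeric(1)))
      best <- min(best, pen)
    }
    best
  }
  for (i in 1:6) {
    tg <- c(t = random_dna_str(80))
    got <- scan_mirna_targets(m, tg, max_penalty = Inf, best_only = TRUE)
    expect_equal(got$penalty, bulge_oracle(m[[1]], tg[[1]]))
  }
})

test_that("dinucleotide shuffle preserves composition and kills planted sites", {
  set.seed(16)
  s <- random_dna_str(400)
  sh <- dinucleotide_shuffle(s)
  din <- function(x) table(substring(x, 1:(nchar(x) - 1), 2:nchar(x)))
  expect_equal(din(sh), din(s))
  expect_false(identical(sh, s))
})
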