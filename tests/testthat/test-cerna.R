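test_that("precursor homology exclusion matches an exhaustive diagonal oracle", {
  set.seed(21)
  # a 50-strong lncRNA set; one carries a 60 nt precursor fragment at 95 %
  lncs <- stats::setNames(vapply(1:50, function(i) random_dna_str(500),
                                 character(1)), paste0("L", 1:50))
  prec <- c(hp = random_dna_str(60))
  frag <- strsplit(prec[[1]], "")[[1]]
  mut <- sample(60, 3)                       # 95 % identity
  for (p in mut) frag[p] <- setdiff(c("A", "C", "G", "T"), frag[p])[1]
  host <- "L7"
  s <- lncs[[host]]
  substr(s, 101, 160) <- paste(frag, collapse = "")
  lncs[[host]] <- s
  kept <- exclude_precursor_lncrnas(lncs, prec)
  expect_equal(attr(kept, "removed")$lncrna, host)
  expect_false(host %in% names(kept))
  # exhaustive diagonal-scan oracle over every (lncRNA, precursor) pair
  oracle_hit <- function(lseq, pseq, win = 50, idmin = 0.9) {
    lc <- strsplit(lseq, "")[[1]]; pc <- strsplit(pseq, "")[[1]]
    nL <- length(lc); nP <- length(pc)
    for (d in (1 - nP):(nL - win)) {
      p_lo <- max(1, 1 - d); p_hi <- min(nP, nL - d)
      if (p_hi - p_lo + 1 < win) next
      mvec <- lc[(p_lo:p_hi) + d] == pc[p_lo:p_hi]
      cs <- cumsum(c(0, mvec))
      len <- length(mvec)
      if (any((cs[(win + 1):(len + 1)] - cs[1:(len - win + 1)]) / win >=
              idmin)) return(TRUE)
    }
    FALSE
  }
  oracle <- names(lncs)[vapply(lncs, oracle_hit, logical(1),
                               pseq = prec[[1]])]
  expect_equal(attr(kept, "removed")$lncrna, oracle)
  # trivial cases
  same <- c(X = prec[[1]])
  expect_equal(nrow(attr(exclude_precursor_lncrnas(same, prec),
                         "removed")), 1)
  untouched <- exclude_precursor_lncrnas(lncs, character(0))
  expect_equal(names(untouched), names(lncs))
})

test_that("triplet assembly equals exhaustive enumeration on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    n_l <- 8; n_g <- 20; n_m <- 4
    lids <- paste0("L", 1:n_l); gids <- paste0("G", 1:n_g)
    mids <- paste0("M", 1:n_m)
    de_l <- tibble::tibble(transcript = sample(lids, 5),
                           log2fc = sample(c(-2, 2), 5, TRUE))
    de_g <- tibble::tibble(transcript = sample(gids, 12),
                           log2fc = sample(c(-2, 2), 12, TRUE))
    de_m <- tibble::tibble(transcript = sample(mids, 2),
                           log2fc = sample(c(-2, 2), 2, TRUE))
    rand_sites <- function(targets, nn) {
      tibble::tibble(mirna = sample(mids, nn, TRUE),
                     target = sample(targets, nn, TRUE),
                     start = sample(100, nn), penalty = runif(nn, 0, 3)) |>
        dplyr::distinct(mirna, target, .keep_all = TRUE)
    }
    ls <- rand_sites(lids, 12)
    ms <- rand_sites(gids, 25)
    des <- default_design()
    v <- matrix(stats::rlnorm((n_l + n_g) * 12, 3, 1), n_l + n_g, 12,
                dimnames = list(c(lids, gids), des$sample))
    x <- expression_matrix(v, des, unit = "fpkm")
    r_min <- 0.3
    got <- build_triplets(de_l, de_g, de_m, ls, ms, x, r_min = r_min)
    # exhaustive (L, M, G) enumeration with predicate re-evaluation
    lv <- log2(v + 1)
    keys <- character(0)
    for (L in lids) for (M in mids) for (G in gids) {
      if (!L %in% de_l$transcript || !G %in% de_g$transcript) next
      if (!M %in% de_m$transcript) next
      if (!any(ls$mirna == M & ls$target == L)) next
      if (!any(ms$mirna == M & ms$target == G)) next
      if (cor(lv[L, ], lv[G, ]) < r_min) next
      keys <- c(keys, paste(L, M, G))
    }
    expect_setequal(paste(got$lncrna, got$mirna, got$mrna), keys)
  }
})

test_that("raising r_min or lowering max_penalty never adds triplets", {
  set.seed(40)
  m <- c(miR1 = random_dna_str(21), miR2 = random_dna_str(21))
  hosts <- stats::setNames(
    c(vapply(1:3, function(i) host_with_site(m[[1]]), character(1)),
      vapply(1:3, function(i) host_with_site(m[[2]]), character(1))),
    paste0("T", 1:6))
  lids <- c("T1", "T4"); gids <- setdiff(names(hosts), lids)
  sites <- scan_mirna_targets(m, hosts, max_penalty = 3)
  des <- default_design()
  base <- stats::rlnorm(12, 3, 1)
  v <- outer(seq_len(6), seq_len(12),
             function(i, j) base[j] * i)
  dimnames(v) <- list(names(hosts), des$sample)
  x <- expression_matrix(v, des, unit = "fpkm")
  de_all <- tibble::tibble(transcript = names(hosts), log2fc = 2)
  de_m <- tibble::tibble(transcript = names(m), log2fc = -2)
  loose <- build_triplets(de_all[de_all$transcript %in% lids, ],
                          de_all[de_all$transcript %in% gids, ], de_m,
                          dplyr::filter(sites, target %in% lids),
                          dplyr::filter(sites, target %in% gids),
                          x, r_min = 0.5)
  tight <- build_triplets(de_all[de_all$transcript %in% lids, ],
                          de_all[de_all$transcript %in% gids, ], de_m,
                          dplyr::filter(sites, target %in% lids,
                                        penalty <= 0),
                          dplyr::filter(sites, target %in% gids,
                                        penalty <= 0),
                          x, r_min = 0.99)
  expect_true(all(paste(tight$lncrna, tight$mirna, tight$mrna) %in%
                    paste(loose$lncrna, loose$mirna, loose$mrna)))
})

test_that("the planted two-star topology is recovered and exported losslessly", {
  set.seed(41)
  m <- c(miR1 = random_dna_str(21), miR2 = random_dna_str(21))
  lnc <- c(L1 = host_with_site(m[[1]]), L2 = host_with_site(m[[2]]))
  mr <- stats::setNames(
    c(vapply(1:7, function(i) host_with_site(m[[1]]), character(1)),
      vapply(1:7, function(i) host_with_site(m[[2]]), character(1))),
    paste0("G", 1:14))
  ls <- scan_mirna_targets(m, lnc)
  ms <- scan_mirna_targets(m, mr)
  des <- default_design()
  base <- stats::rlnorm(12, 3, 1)
  v <- matrix(rep(base, each = 16), 16, 12,
              dimnames = list(c(names(lnc), names(mr)), des$sample))
  v <- v * (1 + 0.001 * stats::rnorm(length(v)))  # near-perfect correlation
  x <- expression_matrix(v, des, unit = "fpkm")
  tri <- build_triplets(
    tibble::tibble(transcript = names(lnc), log2fc = 2),
    tibble::tibble(transcript = names(mr), log2fc = 2),
    tibble::tibble(transcript = names(m), log2fc = -2),
    ls, ms, x, r_min = 0.95)
  # 2 miRNAs x (1 lncRNA + 7 mRNAs) each: two disjoint stars
  net <- cerna_network(tri)
  expect_equal(nrow(net$nodes), 18)
  comp <- igraph::components(net$graph)
  expect_equal(comp$no, 2)
  mem <- split(names(comp$membership), comp$membership)
  expect_true(all(vapply(mem, function(g) sum(g %in% names(m)) == 1,
                         logical(1))))
  expect_true(all(tri$direction_consistent))
  # counting: 8 triplets over one miRNA -> 7 nodes, 14 edges
  tri1 <- dplyr::filter(tri, mirna == "miR1",
                        mrna %in% paste0("G", 1:4))
  net1 <- cerna_network(tri1)
  expect_equal(nrow(tri1), 4)  # 1 lncRNA x 4 mRNAs here
  # round-trip through the edge-list file
  tf <- tempfile(fileext = ".tsv")
  write_network(net, tf)
  back <- triplets_from_network(read_network(tf))
  expect_setequal(paste(tri$lncrna, tri$mirna, tri$mrna),
                  paste(back$lncrna, back$mirna, back$mrna))
  # empty triplets export an empty, readable file
  e <- cerna_network(tri[0, ])
  tf2 <- tempfile(fileext = ".tsv")
  write_network(e, tf2)
  expect_equal(nrow(read_network(tf2)$edges), 0)
})
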