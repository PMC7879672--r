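test_that("ORF scan follows the ATG-to-stop, forward-frame contract", {
  # AT repeats contain no ATG-initiated ORF
  expect_equal(longest_orf(strrep("AT", 300)), 0L)
  # a planted 399-codon ORF inside UTRs is found at its exact length
  set.seed(1)
  orf <- nitrolnc:::coding_orf(399)
  expect_gte(longest_orf(paste0("CCCTCC", orf, "TTTCCC")), 399L)
  # strandedness: an ORF on the reverse strand does not trigger the call
  fwd <- "ATGGGGTGTCCCTAA"               # 4-codon ORF forward
  rev <- revcomp(fwd)                    # no forward ATG here
  expect_gte(longest_orf(fwd), 4L)
  expect_equal(longest_orf(rev), 0L)
  expect_error(call_coding_potential("ACGTX"), "malformed")
})

test_that("Fickett TESTCODE separates coding-like from random composition", {
  set.seed(2)
  rand <- vapply(1:15, function(i) random_dna_str(600), character(1))
  cod <- vapply(1:15, function(i) nitrolnc:::coding_decoy_seq(600),
                character(1))
  expect_true(all(fickett_score(rand) < 0.95))
  expect_true(all(fickett_score(cod) >= 0.95))
  cp <- call_coding_potential(c(a = rand[1], b = cod[1]))
  expect_equal(cp$composition_call, c("noncoding", "coding"))
  expect_true(all(is.finite(cp$fickett_score)))
})

test_that("filter cascade matches a brute-force application of the five predicates", {
  cfg <- sim_config(seed = 17, n_genes = 40, n_lincrna = 30, n_antisense = 0,
                    n_coding_decoys = 20)
  st <- simulate_study(cfg)
  a <- st$annotation
  assembled <- dplyr::filter(a, source == "assembled")
  known <- dplyr::filter(a, source == "known")
  ab <- fpkm(st$expression)
  out <- run_filter_cascade(assembled, st$sequences, ab, known)

  # independent predicate evaluation, combined in order
  seqs <- st$sequences[assembled$id]
  p1 <- nchar(seqs) >= 200
  p2 <- rowSums(ab$values[assembled$id, , drop = FALSE] >= 0.5) >= 1
  p3 <- vapply(seq_len(nrow(assembled)), function(i) {
    !any(vapply(seq_len(nrow(known)), function(j)
      overlaps_brute(assembled[i, ], known[j, ], opposite_strand = FALSE),
      logical(1)))
  }, logical(1))
  p4 <- fickett_score(seqs) < 0.95
  p5 <- longest_orf(seqs) < 100
  verdict <- ifelse(!p1 | !p2 | !p3, "rejected",
                    ifelse(p4 & p5, "lncRNA",
                           ifelse(!p4 & !p5, "rejected", "TUCP")))
  expect_equal(out$verdict, unname(verdict))
  # planted sensitivity/specificity at default thresholds
  truth <- dplyr::left_join(out, st$truth$types, by = "id")
  planted <- truth$type %in% c("lincRNA", "antisense") & truth$length >= 200 &
    p2[match(truth$id, names(p2))]
  expect_equal(mean(truth$verdict[planted] == "lncRNA"), 1)
  expect_equal(mean(truth$verdict[truth$type == "decoy"] == "rejected"), 1)
  # partition invariant
  expect_equal(sum(out$verdict %in% c("lncRNA", "TUCP", "rejected")),
               nrow(assembled))
  expect_true(all(!is.na(out$rejection_step[out$verdict == "rejected"])))
  expect_true(all(out$lncrna_class[out$verdict == "lncRNA"] != "none"))
})

test_that("cascade is monotone, order-invariant and rejects same-strand overlap", {
  cfg <- sim_config(seed = 23, n_genes = 30, n_lincrna = 12, n_antisense = 4,
                    n_coding_decoys = 4)
  st <- simulate_study(cfg)
  a <- st$annotation
  assembled <- dplyr::filter(a, source == "assembled")
  known <- dplyr::filter(a, source == "known")
  ab <- fpkm(st$expression)
  out <- run_filter_cascade(assembled, st$sequences, ab, known)
  # order-invariance
  perm <- sample(nrow(assembled))
  out_p <- run_filter_cascade(assembled[perm, ], st$sequences, ab, known)
  expect_equal(out_p[order(out_p$id), ], out[order(out$id), ])
  # monotone cascade: survivors at tighter thresholds are a subset
  tight <- run_filter_cascade(assembled, st$sequences, ab, known,
                              min_length = 400)
  expect_true(all(tight$id[tight$verdict == "lncRNA"] %in%
                    out$id[out$verdict == "lncRNA"]))
  # a transcript identical to a known gene is rejected at step 3
  g1 <- known[1, ]
  fake <- g1; fake$id <- "COPY_OF_GENE"; fake$source <- "assembled"
  seqs2 <- c(st$sequences, COPY_OF_GENE = st$sequences[[g1$id]])
  ab2 <- ab
  ab2$values <- rbind(ab2$values,
                      COPY_OF_GENE = ab2$values[g1$id, ])
  res <- run_filter_cascade(fake, seqs2, ab2, known)
  expect_equal(res$verdict, "rejected")
  expect_equal(res$rejection_step, 3L)
  # a 150 nt noncoding transcript is rejected at step 1
  short <- assembled[1, ]; short$id <- "SHORTIE"
  seqs3 <- c(st$sequences, SHORTIE = substr(st$sequences[[assembled$id[1]]], 1, 150))
  ab3 <- ab; ab3$values <- rbind(ab3$values, SHORTIE = ab3$values[1, ])
  res3 <- run_filter_cascade(short, seqs3, ab3, known)
  expect_equal(res3$rejection_step, 1L)
  # missing expression row is an input error
  expect_error(run_filter_cascade(fake, seqs2, ab, known), "inconsistent")
})

test_that("lincRNA/antisense classification matches the brute-force double loop", {
  cfg <- sim_config(seed = 29, n_genes = 40, n_lincrna = 20, n_antisense = 5,
                    n_coding_decoys = 0)
  ann <- simulate_annotation(cfg)
  a <- ann$annotation
  cand <- dplyr::filter(a, type %in% c("lincRNA", "antisense"))
  known <- dplyr::filter(a, type == "gene")
  cls <- classify_lncrna(cand, known)
  expect_equal(sum(cls == "lincRNA"), 20)
  expect_equal(sum(cls == "antisense"), 5)
  oracle <- vapply(seq_len(nrow(cand)), function(i) {
    any(vapply(seq_len(nrow(known)), function(j)
      overlaps_brute(cand[i, ], known[j, ], opposite_strand = TRUE),
      logical(1)))
  }, logical(1))
  expect_equal(cls == "antisense", oracle)
})
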