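test_that("annotation generator respects placement contracts", {
  cfg <- sim_config(seed = 7, n_genes = 50, n_lincrna = 20, n_antisense = 5,
                    n_coding_decoys = 5)
  ann <- simulate_annotation(cfg)
  a <- ann$annotation
  expect_equal(nrow(a), 80)
  # sequence length equals summed exon length
  lens <- vapply(a$exons, function(e) sum(e$end - e$start + 1), numeric(1))
  expect_equal(unname(nchar(ann$sequences[a$id])), unname(lens))
  # brute-force interval scan: no same-strand gene/lincRNA exon overlap,
  # exactly five opposite-strand antisense overlaps
  genes <- dplyr::filter(a, type == "gene")
  lincs <- dplyr::filter(a, type == "lincRNA")
  anti <- dplyr::filter(a, type == "antisense")
  n_same <- 0; n_opp <- 0
  for (i in seq_len(nrow(lincs))) for (j in seq_len(nrow(genes))) {
    if (lincs$chrom[i] != genes$chrom[j]) next
    e1 <- lincs$exons[[i]]; e2 <- genes$exons[[j]]
    hit <- any(outer(e1$start, e2$end, `<=`) & outer(e1$end, e2$start, `>=`))
    if (hit) n_same <- n_same + 1
  }
  for (i in seq_len(nrow(anti))) for (j in seq_len(nrow(genes))) {
    if (anti$chrom[i] != genes$chrom[j]) next
    e1 <- anti$exons[[i]]; e2 <- genes$exons[[j]]
    hit <- any(outer(e1$start, e2$end, `<=`) & outer(e1$end, e2$start, `>=`))
    if (hit) {
      n_opp <- n_opp + 1
      expect_true(anti$strand[i] != genes$strand[j])
    }
  }
  expect_equal(n_same, 0)
  expect_equal(n_opp, 5)
  # coding decoys carry a long ORF; noncoding transcripts do not
  expect_true(all(longest_orf(ann$sequences[dplyr::filter(a, type == "decoy")$id]) >= 100))
  expect_true(all(longest_orf(ann$sequences[c(lincs$id, anti$id)]) < 60))
})

test_that("annotation generator handles the genes-only and empty-genome cases", {
  cfg <- sim_config(seed = 2, n_genes = 10, n_lincrna = 0, n_antisense = 0,
                    n_coding_decoys = 0)
  ann <- simulate_annotation(cfg)
  expect_equal(sort(unique(ann$annotation$type)), "gene")
  expect_equal(nrow(dplyr::filter(ann$truth, type != "gene")), 0)
  tiny <- sim_config(seed = 2, n_genes = 400, n_chromosomes = 1,
                     chromosome_length = 5e4)
  expect_error(simulate_annotation(tiny), "genome too small")
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 13, n_genes = 30, n_lincrna = 8, n_antisense = 2,
                    n_coding_decoys = 3, n_lines = 30, n_snps = 100)
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  ann <- simulate_annotation(cfg)
  expect_identical(simulate_expression(ann, cfg),
                   simulate_expression(ann, cfg))
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  g <- simulate_genotypes(cfg)
  expect_identical(simulate_phenotypes(g, cfg),
                   simulate_phenotypes(g, cfg))
  # file-level determinism of the GFF3 stream
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_gff3(ann$annotation, f1); write_gff3(ann$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("expression simulator plants the stated condition effect", {
  cfg <- sim_config(seed = 5, n_genes = 40, n_lincrna = 10, n_antisense = 2,
                    n_coding_decoys = 2, de_fraction = 0.2)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(ann, cfg)
  expect_equal(ncol(ex$expression$values), 12)  # 2 tissues x 2 N x 3 reps
  expect_true(all(ex$truth$transcript %in% ann$annotation$id))
  # null model: de_fraction = 0 leaves the truth table empty
  cfg0 <- sim_config(seed = 5, n_genes = 40, n_lincrna = 10,
                     n_antisense = 2, n_coding_decoys = 2, de_fraction = 0)
  ex0 <- simulate_expression(ann, cfg0)
  expect_equal(nrow(ex0$truth), 0)
  # a de_fraction too small to select any transcript is a config conflict
  cfg_bad <- sim_config(seed = 5, n_genes = 2, n_lincrna = 0,
                        n_antisense = 0, n_coding_decoys = 0,
                        de_fraction = 0.1)
  ann2 <- simulate_annotation(cfg_bad)
  expect_error(simulate_expression(ann2, cfg_bad), "conflict")
})

test_that("planted log2 fold change of 1 doubles the LN mean (Monte Carlo)", {
  # 10 000 planted transcripts at high baseline so the mean ratio is tight
  set.seed(1)
  cfg <- sim_config(seed = 3, log2fc_effect = 1, nb_dispersion = 0.05,
                    baseline_meanlog = 6, baseline_sdlog = 0.2)
  des <- cfg$design
  n <- 10000
  mu <- stats::rlnorm(n, 6, 0.2)
  hn <- stats::rnbinom(n, mu = mu, size = 20)
  ln <- stats::rnbinom(n, mu = mu * 2, size = 20)
  ratio <- mean(ln) / mean(hn)
  expect_lt(abs(ratio - 2), 0.1)  # within 5 % of 2.0
})

test_that("miRNA simulator plants sites exactly as specified", {
  cfg <- sim_config(seed = 9, n_mirna = 2)
  hosts <- c(H1 = random_dna_str(400), H2 = random_dna_str(400))
  plan <- tibble::tibble(mirna = c(1L, 2L), host = c("H1", "H2"),
                         mismatches = c(0L, 3L))
  mir <- simulate_mirna(cfg, hosts, mre_plan = plan)
  tr <- mir$truth$mre
  # zero-mismatch site is the exact reverse complement of the mature miRNA
  s0 <- substr(mir$sequences[["H1"]], tr$position[1],
               tr$position[1] + cfg$mirna_length - 1)
  expect_identical(s0, revcomp(mir$mature[[tr$mirna[1]]]))
  # three mismatches, none at miRNA positions 10-11
  s3 <- substr(mir$sequences[["H2"]], tr$position[2],
               tr$position[2] + cfg$mirna_length - 1)
  ref <- strsplit(revcomp(mir$mature[[tr$mirna[2]]]), "")[[1]]
  got <- strsplit(s3, "")[[1]]
  mm_site <- which(ref != got)
  mm_mirna <- cfg$mirna_length - mm_site + 1
  expect_equal(length(mm_site), 3)
  expect_false(any(mm_mirna %in% 10:11))
  # excessive mismatches are an invalid spec
  bad <- tibble::tibble(mirna = 1L, host = "H1", mismatches = 30L)
  expect_error(simulate_mirna(cfg, hosts, mre_plan = bad), "invalid spec")
})

test_that("genotype simulator hits its allele-frequency and missingness targets", {
  cfg <- sim_config(seed = 21, n_lines = 10000, n_snps = 20,
                    maf_range = c(0.3, 0.3), missing_rate = 0)
  g <- simulate_genotypes(cfg)
  expect_false(anyNA(g$dosage))
  st <- snp_stats(g)
  expect_true(all(abs(st$maf - 0.3) <= 0.01))  # law of large numbers
  cfg2 <- sim_config(seed = 21, n_lines = 255, n_snps = 300,
                     missing_rate = 0.1)
  g2 <- simulate_genotypes(cfg2)
  expect_equal(nrow(g2$dosage), 255)           # the association panel size
  expect_lt(abs(mean(is.na(g2$dosage)) - 0.1), 0.01)
  expect_true(all(g2$map$pos == sort(g2$map$pos)[rank(g2$map$pos)]))
})

test_that("phenotype simulator produces the 17-trait two-treatment layout", {
  cfg <- sim_config(seed = 4, n_lines = 40, n_snps = 100, n_reps = 3)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  cnt <- dplyr::count(ph$phenotypes, line, trait, treatment)
  expect_true(all(cnt$n == 3))
  expect_equal(length(unique(ph$phenotypes$trait)), 17)
  expect_equal(sort(unique(ph$phenotypes$treatment)), c("HN", "LN"))
  # h2_target = 0 with no QTLs gives pure noise
  cfg0 <- sim_config(seed = 4, n_lines = 40, n_snps = 100, h2_target = 0,
                     traits = "SL")
  ph0 <- simulate_phenotypes(g, cfg0)
  h <- heritability(ph0$phenotypes, "SL", "LN")
  expect_lt(h$H2, 0.2)
  # invalid variance budget
  cfgbad <- sim_config(seed = 4, n_lines = 40, n_snps = 100, traits = "SL",
                       qtl_spec = tibble::tibble(
                         snp = 1:2, trait = "SL", ve = c(0.6, 0.6)))
  expect_error(simulate_phenotypes(g, cfgbad), "invalid spec")
})

test_that("phenotype simulator recovers the target heritability", {
  h2 <- vapply(1:8, function(s) {
    cfg <- sim_config(seed = s, n_lines = 250, n_snps = 200, n_reps = 3,
                      h2_target = 0.6, traits = "SL", missing_rate = 0)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(g, cfg)
    heritability(ph$phenotypes, "SL", "LN")$H2
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.6), 0.1)
})

test_that("truth tables reconcile with the emitted study", {
  cfg <- sim_config(seed = 31, n_genes = 40, n_lincrna = 10,
                    n_antisense = 3, n_coding_decoys = 3, n_lines = 40,
                    n_snps = 120, n_qtl = 1)
  st <- simulate_study(cfg)
  ids <- st$annotation$id
  expect_true(all(st$truth$de$transcript %in% ids))
  expect_true(all(st$truth$mre$host %in% ids))
  expect_true(all(st$truth$qtl$snp %in% colnames(st$genotypes$dosage)))
  expect_true(all(st$truth$precursor$lncrna %in% ids))
  # planted site positions lie within their hosts
  with(st$truth$mre, expect_true(all(
    position >= 1 &
      position + cfg$mirna_length - 1 <= nchar(st$sequences[host]))))
})
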