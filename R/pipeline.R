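# End-to-end orchestration: simulate -> identify -> differential expression
# -> targets -> ceRNA on the expression branch, and phenotype -> GWAS ->
# LD decay -> integration on the association branch, from one configuration
# with a single fanned-out seed and a run manifest.

#' Pipeline configuration
#'
#' A [sim_config()] plus every analysis threshold. Stage toggles allow the
#' ceRNA branch to be disabled independently of the integration branch.
#'
#' @param config A [sim_config()] describing the synthetic study.
#' @param min_length,min_fpkm,min_samples,orf_codons,fickett_threshold
#'   Identification cascade thresholds.
#' @param q_alpha DE significance threshold.
#' @param window Cis window (bp).
#' @param r_min Trans / ceRNA correlation threshold.
#' @param max_penalty miRNA site penalty ceiling.
#' @param maf_min,missing_max Marker QC thresholds.
#' @param k_pcs Structure covariates (principal components).
#' @param p_threshold GWAS significance threshold.
#' @param r2_threshold LD-decay threshold.
#' @param gwas_traits Traits scanned (on LNTI and LN line means).
#' @param run_cerna Toggle for the ceRNA stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(config = sim_config(),
                            min_length = 200, min_fpkm = 0.5,
                            min_samples = 1, orf_codons = 100,
                            fickett_threshold = 0.95,
                            q_alpha = 0.05, window = 1e5, r_min = 0.95,
                            max_penalty = 3, maf_min = 0.01,
                            missing_max = 0.2, k_pcs = 2,
                            p_threshold = 10^-4.6, r2_threshold = 0.1,
                            gwas_traits = NULL, run_cerna = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate cross-file consistency of pipeline inputs
#'
#' Reports (never errors): transcripts present in the annotation but
#' missing from sequences or the expression matrix, and line ids not shared
#' between genotypes and phenotypes.
#'
#' @param annotation Annotation tibble.
#' @param sequences Named character vector.
#' @param expression An [expression_matrix()].
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes Long phenotype tibble.
#' @return Tibble of violations (`check`, `item`); zero rows when
#'   consistent.
#' @export
validate_inputs <- function(annotation = NULL, sequences = NULL,
                            expression = NULL, genotypes = NULL,
                            phenotypes = NULL) {
  v <- list()
  add <- function(check, items) {
    if (length(items))
      v[[length(v) + 1]] <<- tibble(check = check, item = items)
  }
  if (is.null(annotation)) add("missing_input", "annotation")
  if (is.null(sequences)) add("missing_input", "sequences")
  if (is.null(expression)) add("missing_input", "expression")
  if (is.null(genotypes)) add("missing_input", "genotypes")
  if (is.null(phenotypes)) add("missing_input", "phenotypes")
  if (!is.null(annotation) && !is.null(sequences))
    add("annotation_without_sequence",
        setdiff(annotation$id, names(sequences)))
  if (!is.null(annotation) && !is.null(expression))
    add("annotation_without_expression",
        setdiff(annotation$id, rownames(expression$values)))
  if (!is.null(genotypes) && !is.null(phenotypes)) {
    add("phenotype_line_not_genotyped",
        setdiff(unique(phenotypes$line), genotypes$lines))
    add("genotyped_line_without_phenotype",
        setdiff(genotypes$lines, unique(phenotypes$line)))
  }
  out <- bind_rows(v)
  if (nrow(out) == 0) out <- tibble(check = character(0), item = character(0))
  out
}

#' Run the full pipeline on a configuration
#'
#' Stages in dependency order: simulate, identify, differential expression
#' (mRNA/lncRNA and miRNA, per tissue), cis/trans targets, ceRNA network
#' (toggleable), phenotype statistics, GWAS on LN line means and on the
#' low-nitrogen tolerance index, LD decay, candidate windows and the
#' GWAS-by-expression intersection. Reruns with an identical configuration
#' are identical; `outdir` additionally writes every artifact (GFF3, FASTA,
#' TSV, VCF, JSON truth, manifest).
#'
#' @param pcfg A [pipeline_config()] (a bare [sim_config()] is promoted
#'   with default thresholds).
#' @param outdir Optional output directory.
#' @return List of class `pipeline_run`: `study`, per-stage `results`, and
#'   a `manifest` tibble of stage row counts and parameters.
#' @export
run_pipeline <- function(pcfg = pipeline_config(), outdir = NULL) {
  if (inherits(pcfg, "sim_config")) pcfg <- pipeline_config(pcfg)
  stopifnot(inherits(pcfg, "pipeline_config"))
  cfg <- pcfg$config

  study <- simulate_study(cfg)
  ann <- study$annotation
  expr <- study$expression

  # identification: assembled transcripts against the known gene models
  assembled <- ann |> filter(.data$source == "assembled")
  known <- ann |> filter(.data$source == "known")
  ab <- fpkm(expr)
  cascade <- run_filter_cascade(assembled, study$sequences, ab, known,
                                min_length = pcfg$min_length,
                                min_fpkm = pcfg$min_fpkm,
                                min_samples = pcfg$min_samples,
                                orf_codons = pcfg$orf_codons,
                                fickett_threshold = pcfg$fickett_threshold)
  lnc_ids <- cascade$id[cascade$verdict == "lncRNA"]

  # differential expression per tissue (transcripts, then miRNAs)
  norm <- normalize_counts(expr)
  tissues <- unique(cfg$design$tissue)
  de <- map(setNames(tissues, tissues),
            ~ test_de(norm, .x, alpha = pcfg$q_alpha))
  mir_norm <- tryCatch(normalize_counts(study$mirna$counts),
                       error = function(e) study$mirna$counts)
  de_mir <- map(setNames(tissues, tissues),
                ~ test_de(mir_norm, .x, alpha = pcfg$q_alpha))

  de_all <- bind_rows(de)
  de_sig <- de_all |> filter(.data$significant)
  de_lnc <- de_sig |> filter(.data$transcript %in% lnc_ids) |>
    distinct(.data$transcript, .keep_all = TRUE)
  gene_ids <- known$id
  de_gene <- de_sig |> filter(.data$transcript %in% gene_ids) |>
    distinct(.data$transcript, .keep_all = TRUE)
  de_mir_sig <- bind_rows(de_mir) |> filter(.data$significant) |>
    distinct(.data$transcript, .keep_all = TRUE)

  # targets of the differentially expressed lncRNAs
  lnc_ann <- ann |> filter(.data$id %in% de_lnc$transcript)
  logm <- ab
  cis <- find_cis_pairs(lnc_ann, known, logm, window = pcfg$window)
  trans <- find_trans_pairs(lnc_ann$id, gene_ids, logm, r_min = pcfg$r_min)

  # ceRNA branch
  cerna <- NULL
  if (isTRUE(pcfg$run_cerna)) {
    lnc_seqs <- study$sequences[lnc_ids]
    kept <- exclude_precursor_lncrnas(lnc_seqs, study$mirna$precursors)
    mir_mat <- study$mirna$mature
    lnc_sites <- scan_mirna_targets(mir_mat, kept,
                                    max_penalty = pcfg$max_penalty)
    mrna_sites <- scan_mirna_targets(
      mir_mat, study$sequences[intersect(gene_ids, de_gene$transcript)],
      max_penalty = pcfg$max_penalty)
    triplets <- build_triplets(de_lnc, de_gene, de_mir_sig,
                               lnc_sites, mrna_sites, logm,
                               r_min = pcfg$r_min)
    cerna <- cerna_network(triplets)
  }

  # association branch
  phen <- study$phenotypes
  pheno_summary <- summarize_traits(phen)
  idx <- lnti(phen)
  geno_f <- filter_markers(study$genotypes, maf_min = pcfg$maf_min,
                           missing_max = pcfg$missing_max)
  K <- kinship(geno_f)
  pcs <- structure_covariates(geno_f, k = pcfg$k_pcs)
  traits <- pcfg$gwas_traits %||% unique(study$truth$qtl$trait)
  if (length(traits) == 0) traits <- cfg$traits[1]
  scans <- list()
  for (tr in traits) {
    ln_means <- phen |> filter(.data$trait == tr, .data$treatment == "LN") |>
      group_by(.data$line) |> summarise(m = mean(.data$value))
    y_ln <- setNames(ln_means$m, ln_means$line)
    idx_tr <- idx |> filter(.data$trait == tr, !.data$excluded)
    y_idx <- setNames(idx_tr$lnti, idx_tr$line)
    scans[[paste0(tr, ":LN")]] <-
      mlm_scan(geno_f, y_ln, K, pcs, p_threshold = pcfg$p_threshold)
    scans[[paste0(tr, ":LNTI")]] <-
      mlm_scan(geno_f, y_idx, K, pcs, p_threshold = pcfg$p_threshold)
  }
  ld <- ld_decay(geno_f, r2_threshold = pcfg$r2_threshold)
  decay_d <- ld$average
  if (!is.finite(decay_d)) decay_d <- ld$max_dist

  sig_snps <- bind_rows(map(scans, ~ .x$results |>
                              filter(.data$significant)), .id = "scan") |>
    distinct(.data$snp, .data$chrom, .data$pos, .keep_all = TRUE)
  windows <- build_windows(sig_snps, decay_d, ann,
                           chrom_lengths = setNames(
                             rep(cfg$chromosome_length, cfg$n_chromosomes),
                             paste0("chr", seq_len(cfg$n_chromosomes))))
  candidates <- intersect_with_de(windows, de_all, alpha = pcfg$q_alpha)
  links <- link_lncrna_to_candidates(candidates, cis, trans)

  results <- list(cascade = cascade, de = de, de_mirna = de_mir,
                  cis = cis, trans = trans, cerna = cerna,
                  pheno_summary = pheno_summary, lnti = idx,
                  scans = scans, ld = ld, windows = windows,
                  candidates = candidates, links = links)
  manifest <- tibble(
    stage = c("simulate", "identify", "de", "targets", "cerna", "pheno",
              "gwas", "ld_decay", "integrate"),
    rows = c(nrow(ann), nrow(cascade), nrow(de_sig),
             nrow(cis) + nrow(trans),
             if (is.null(cerna)) NA_integer_ else nrow(cerna$edges),
             nrow(pheno_summary), nrow(sig_snps), nrow(ld$per_chrom),
             nrow(candidates)),
    seed = cfg$seed,
    params = c(
      sprintf("n_genes=%d", cfg$n_genes),
      sprintf("min_length=%g;min_fpkm=%g", pcfg$min_length, pcfg$min_fpkm),
      sprintf("q_alpha=%g", pcfg$q_alpha),
      sprintf("window=%g;r_min=%g", pcfg$window, pcfg$r_min),
      sprintf("max_penalty=%g", pcfg$max_penalty),
      sprintf("n_reps=%d", cfg$n_reps),
      sprintf("maf_min=%g;missing_max=%g;k_pcs=%d;p_threshold=%g",
              pcfg$maf_min, pcfg$missing_max, pcfg$k_pcs,
              pcfg$p_threshold),
      sprintf("r2_threshold=%g;decay=%g", pcfg$r2_threshold, decay_d),
      sprintf("alpha=%g", pcfg$q_alpha)))

  run <- structure(list(study = study, results = results,
                        manifest = manifest, config = pcfg),
                   class = "pipeline_run")
  if (!is.null(outdir)) write_pipeline_outputs(run, outdir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$manifest)
  invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' @param run A [run_pipeline()] result.
#' @param outdir Directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_gff3(run$study$annotation, p("annotation.gff3"))
  write_fasta(run$study$sequences, p("transcripts.fa"))
  write_fasta(run$study$mirna$mature, p("mirna_mature.fa"))
  if (length(run$study$mirna$precursors))
    write_fasta(run$study$mirna$precursors, p("mirna_precursors.fa"))
  write_expression_tsv(run$study$expression, p("counts.tsv"))
  write_genotypes_vcf(run$study$genotypes, p("genotypes.vcf"))
  write_phenotypes_tsv(run$study$phenotypes, p("phenotypes.tsv"))
  write_truth_json(run$study$truth, p("truth.json"))
  readr::write_tsv(run$results$cascade, p("classification.tsv"))
  readr::write_tsv(bind_rows(run$results$de), p("de_transcripts.tsv"))
  readr::write_tsv(run$results$cis, p("cis_pairs.tsv"))
  readr::write_tsv(run$results$trans, p("trans_pairs.tsv"))
  if (!is.null(run$results$cerna))
    write_network(run$results$cerna, p("cerna_edges.tsv"))
  readr::write_tsv(run$results$pheno_summary, p("trait_summary.tsv"))
  readr::write_tsv(bind_rows(map(run$results$scans, tidy), .id = "scan"),
                   p("association.tsv"))
  readr::write_tsv(run$results$windows, p("candidate_windows.tsv"))
  readr::write_tsv(run$results$candidates, p("consistent_candidates.tsv"))
  readr::write_tsv(run$results$links, p("lncrna_links.tsv"))
  readr::write_tsv(run$manifest, p("manifest.tsv"))
  invisible(outdir)
}
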