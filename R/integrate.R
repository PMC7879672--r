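# GWAS x expression integration: LD-decay candidate windows around
# significant SNPs, intersection with differential-expression calls, and
# the lncRNA -> candidate influence table.

#' Candidate windows around significant association SNPs
#'
#' One window per significant SNP, the closed interval
#' `[pos - decay_d, pos + decay_d]` clipped at the chromosome start;
#' containment is any feature-span overlap with the interval (a feature
#' touching the edge by 1 bp is included). Features may appear in several
#' windows; summaries deduplicate.
#'
#' @param significant Tibble of significant SNPs (columns `snp`, `chrom`,
#'   `pos`; e.g. `tidy(scan) |> filter(significant)`).
#' @param decay_d LD-decay distance in bp (e.g. `glance(ld)$average_decay`).
#' @param annotation Annotation tibble of genes and lncRNAs (columns `id`,
#'   `type`, `chrom`, `start`, `end`).
#' @param chrom_lengths Optional named vector for clipping window ends.
#' @return Tibble: `snp`, `chrom`, `window_start`, `window_end`,
#'   `feature_id`, `feature_type` (one row per SNP-feature pair; windows
#'   with no feature keep one row with `NA` feature).
#' @export
build_windows <- function(significant, decay_d, annotation,
                          chrom_lengths = NULL) {
  if (decay_d <= 0) abort("decay_d must be positive")
  empty <- tibble(snp = character(0), chrom = character(0),
                  window_start = numeric(0), window_end = numeric(0),
                  feature_id = character(0), feature_type = character(0))
  if (nrow(significant) == 0) return(empty)
  if (!all(significant$chrom %in% unique(annotation$chrom)))
    abort("annotation mismatch: SNP on unknown chromosome")
  wins <- significant |>
    transmute(.data$snp, .data$chrom,
              window_start = pmax(1, .data$pos - decay_d),
              window_end = .data$pos + decay_d)
  if (!is.null(chrom_lengths))
    wins$window_end <- pmin(wins$window_end,
                            unname(chrom_lengths[wins$chrom]))
  feats <- annotation |> select(feature_id = "id", feature_type = "type",
                                "chrom", "start", "end")
  out <- left_join(wins, feats, by = "chrom",
                   relationship = "many-to-many") |>
    filter(is.na(.data$feature_id) |
             (.data$start <= .data$window_end &
                .data$end >= .data$window_start))
  # keep empty windows visible with an NA feature row
  covered <- out |> distinct(.data$snp)
  missing <- wins |> filter(!.data$snp %in% covered$snp) |>
    mutate(feature_id = NA_character_, feature_type = NA_character_,
           start = NA_real_, end = NA_real_)
  bind_rows(out, missing) |>
    select("snp", "chrom", "window_start", "window_end", "feature_id",
           "feature_type") |>
    arrange(.data$chrom, .data$window_start, .data$feature_id)
}

#' Intersect candidate windows with differential-expression calls
#'
#' A consistent candidate is a window feature differentially expressed
#' (q below `alpha`) in at least one tissue; its direction is the sign of
#' the log2 fold change (taken from the most significant tissue when both
#' are DE), and `expressed_in_both_tissues` flags DE in both tissues.
#'
#' @param windows A [build_windows()] result.
#' @param de_results [test_de()] results for the tissues, row-bound (or a
#'   list of them).
#' @param alpha DE significance threshold (default 0.05).
#' @return Tibble: `feature_id`, `feature_type`, `snps` (collapsed
#'   supporting SNP ids), `n_snps`, `tissues`, `log2fc`, `direction`,
#'   `expressed_in_both_tissues`; summary counts (up/down/both) in the
#'   `"counts"` attribute.
#' @export
intersect_with_de <- function(windows, de_results, alpha = 0.05) {
  if (is.list(de_results) && !is.data.frame(de_results))
    de_results <- bind_rows(de_results)
  de_sig <- de_results |> filter(.data$q_value < alpha)
  feats <- windows |> filter(!is.na(.data$feature_id))
  hits <- inner_join(feats,
                     de_sig |> select(feature_id = "transcript", "tissue",
                                      "log2fc", "q_value"),
                     by = "feature_id", relationship = "many-to-many")
  if (nrow(hits) == 0) {
    out <- tibble(feature_id = character(0), feature_type = character(0),
                  snps = character(0), n_snps = integer(0),
                  tissues = character(0), log2fc = numeric(0),
                  direction = character(0),
                  expressed_in_both_tissues = logical(0))
    attr(out, "counts") <- c(up = 0L, down = 0L, both = 0L)
    return(out)
  }
  out <- hits |> group_by(.data$feature_id, .data$feature_type) |>
    summarise(
      snps = paste(sort(unique(.data$snp)), collapse = ","),
      n_snps = length(unique(.data$snp)),
      tissues = paste(sort(unique(.data$tissue)), collapse = ","),
      log2fc = .data$log2fc[which.min(.data$q_value)],
      expressed_in_both_tissues = length(unique(.data$tissue)) > 1,
      .groups = "drop") |>
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    select("feature_id", "feature_type", "snps", "n_snps", "tissues",
           "log2fc", "direction", "expressed_in_both_tissues") |>
    arrange(.data$feature_id)
  attr(out, "counts") <- c(
    up = sum(out$direction == "up"),
    down = sum(out$direction == "down"),
    both = sum(out$expressed_in_both_tissues))
  out
}

#' Link lncRNAs to consistent candidate genes in cis or trans
#'
#' For each consistent candidate gene, lists the lncRNAs whose cis or trans
#' target set contains it, labelled by mechanism. Candidates with no
#' targeting lncRNA are absent from the table.
#'
#' @param candidates An [intersect_with_de()] result (gene rows are used).
#' @param cis_pairs A [find_cis_pairs()] result.
#' @param trans_pairs A [find_trans_pairs()] result.
#' @return Tibble: `candidate`, `lncrna`, `mechanism` (`cis`/`trans`),
#'   `evidence` (distance in bp for cis, Pearson r for trans).
#' @export
link_lncrna_to_candidates <- function(candidates, cis_pairs, trans_pairs) {
  genes <- candidates |> filter(.data$feature_type %in% c("gene", "mRNA"))
  cis <- cis_pairs |> filter(.data$gene %in% genes$feature_id) |>
    transmute(candidate = .data$gene, lncrna = .data$lncrna,
              mechanism = "cis", evidence = .data$distance)
  trans <- trans_pairs |> filter(.data$gene %in% genes$feature_id) |>
    transmute(candidate = .data$gene, lncrna = .data$lncrna,
              mechanism = "trans", evidence = .data$pearson_r)
  bind_rows(cis, trans) |>
    arrange(.data$candidate, .data$mechanism, .data$lncrna)
}
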