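# Target assignment for lncRNAs: cis (genomic proximity + correlation),
# trans (correlation only), and miRNA binding sites scored by a plant-style
# complementarity penalty.

# Pearson correlations between selected rows of a log2(x+1) expression
# matrix; returns a function(l_id, g_id) -> r, vectorized.
.expr_correlator <- function(expression, ids_a, ids_b) {
  m <- log2p1(expression$values)
  za <- scale_rows(m[ids_a, , drop = FALSE])
  zb <- scale_rows(m[ids_b, , drop = FALSE])
  n <- ncol(m)
  function(a, b) {
    rowSums(za[a, , drop = FALSE] * zb[b, , drop = FALSE]) / (n - 1)
  }
}

#' Find cis lncRNA--gene pairs within a genomic window
#'
#' All genes whose span lies within `window` bp of the lncRNA span
#' (strand-agnostic distance between closest span edges; 0 when
#' overlapping; the boundary is closed, so a gene starting exactly `window`
#' bp away is included), annotated with the Pearson correlation of
#' log2(abundance + 1) across all samples.
#'
#' @param lncrnas,genes Annotation tibbles (columns `id`, `chrom`, `strand`,
#'   `start`, `end`).
#' @param expression An [expression_matrix()] covering both partners.
#' @param window Window size in bp (default 100 kb).
#' @param r_min Optional correlation filter (`NULL` keeps all pairs).
#' @param inner_exclusion Optional inner radius: pairs closer than this are
#'   dropped (default 0, i.e. off).
#' @return Tibble: `lncrna`, `gene`, `distance`, `side`
#'   (`upstream`/`downstream`/`overlapping`, oriented by lncRNA strand),
#'   `pearson_r`.
#' @export
find_cis_pairs <- function(lncrnas, genes, expression, window = 1e5,
                           r_min = NULL, inner_exclusion = 0) {
  if (nrow(lncrnas) == 0 || nrow(genes) == 0)
    return(tibble(lncrna = character(0), gene = character(0),
                  distance = numeric(0), side = character(0),
                  pearson_r = numeric(0)))
  miss <- setdiff(c(lncrnas$id, genes$id), rownames(expression$values))
  if (length(miss)) abort("expression must cover both partners")
  pairs <- inner_join(
    lncrnas |> select(lncrna = "id", "chrom", lstrand = "strand",
                      lstart = "start", lend = "end"),
    genes |> select(gene = "id", "chrom", gstart = "start", gend = "end"),
    by = "chrom", relationship = "many-to-many") |>
    mutate(overlap = .data$gstart <= .data$lend & .data$gend >= .data$lstart,
           distance = ifelse(.data$overlap, 0,
                             pmax(.data$gstart - .data$lend,
                                  .data$lstart - .data$gend))) |>
    filter(.data$distance <= window, .data$distance >= inner_exclusion) |>
    mutate(left_of = .data$gend < .data$lstart,
           side = case_when(
             overlap ~ "overlapping",
             left_of & lstrand == "+" | !left_of & lstrand == "-" ~ "upstream",
             TRUE ~ "downstream"))
  if (nrow(pairs) == 0)
    return(tibble(lncrna = character(0), gene = character(0),
                  distance = numeric(0), side = character(0),
                  pearson_r = numeric(0)))
  corr <- .expr_correlator(expression, unique(pairs$lncrna),
                           unique(pairs$gene))
  pairs$pearson_r <- corr(pairs$lncrna, pairs$gene)
  if (!is.null(r_min)) pairs <- pairs |> filter(.data$pearson_r > r_min)
  pairs |> select("lncrna", "gene", "distance", "side", "pearson_r")
}

#' Find trans lncRNA--gene pairs by expression correlation
#'
#' Every (lncRNA, gene) pair, on any chromosomes, whose Pearson correlation
#' of log2(abundance + 1) across all samples exceeds `r_min`.
#' Constant-expression rows are excluded (recorded in the `"excluded"`
#' attribute), not an error.
#'
#' @param lncrnas,genes Character vectors of transcript ids (or annotation
#'   tibbles with an `id` column).
#' @param expression An [expression_matrix()].
#' @param r_min Correlation threshold (default 0.95, strict `>`).
#' @return Tibble: `lncrna`, `gene`, `pearson_r`.
#' @export
find_trans_pairs <- function(lncrnas, genes, expression, r_min = 0.95) {
  l_ids <- if (is.data.frame(lncrnas)) lncrnas$id else lncrnas
  g_ids <- if (is.data.frame(genes)) genes$id else genes
  if (ncol(expression$values) < 3) abort("need at least three samples")
  miss <- setdiff(c(l_ids, g_ids), rownames(expression$values))
  if (length(miss)) abort("expression must cover both partners")
  m <- log2p1(expression$values)
  zl <- scale_rows(m[l_ids, , drop = FALSE])
  zg <- scale_rows(m[g_ids, , drop = FALSE])
  excluded <- c(l_ids[rowSums(is.na(zl)) > 0], g_ids[rowSums(is.na(zg)) > 0])
  R <- zl %*% t(zg) / (ncol(m) - 1)
  hit <- which(R > r_min & !is.na(R), arr.ind = TRUE)
  out <- tibble(lncrna = l_ids[hit[, 1]], gene = g_ids[hit[, 2]],
                pearson_r = R[hit]) |>
    filter(.data$lncrna != .data$gene) |>
    arrange(.data$lncrna, .data$gene)
  attr(out, "excluded") <- unique(excluded)
  out
}

# ---- miRNA target scanning --------------------------------------------------

.base_code <- function(s) {
  code <- match(seq_chars(s), c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

# cost[rc_base, target_base]: 0 match, 0.5 G:U wobble, 1 mismatch.
# Rows/cols: A C G T other. rc is the reverse complement of the miRNA, so
# wobble (miRNA G : target U) appears as (rc C : target T), and
# (miRNA U : target G) as (rc A : target G).
.pair_cost <- local({
  m <- matrix(1, 5, 5)
  diag(m)[1:4] <- 0
  m[2, 4] <- 0.5  # rc C vs target T  (miRNA G : target U)
  m[1, 3] <- 0.5  # rc A vs target G  (miRNA U : target G)
  m[5, ] <- 1; m[, 5] <- 1
  m
})

# Exhaustive penalties for one miRNA against one target; returns a list of
# per-offset best penalties and the bulge choice. Positions are weighted
# double at miRNA positions 2-13; mismatch costs 1, G:U wobble 0.5, a
# single-nucleotide target bulge 2.
.scan_one <- function(rc_code, target_code, w_site, bulge_w, allow_bulge) {
  L <- length(rc_code)
  Tn <- length(target_code)
  if (Tn < L) return(NULL)
  n0 <- Tn - L + 1
  # ungapped: cost matrix L x n0
  idx0 <- outer(seq_len(L), seq_len(n0) - 1L, "+")
  M0 <- matrix(.pair_cost[cbind(rep(rc_code, n0), target_code[idx0])],
               L, n0) * w_site
  pen0 <- colSums(M0)
  best <- pen0
  bulge_at <- rep(NA_integer_, n0)
  if (allow_bulge && Tn >= L + 1 && L >= 2) {
    n1 <- Tn - L
    idx1 <- outer(seq_len(L) + 1L, seq_len(n1) - 1L, "+")
    M1 <- matrix(.pair_cost[cbind(rep(rc_code, n1), target_code[idx1])],
                 L, n1) * w_site
    P0 <- apply(M0[, seq_len(n1), drop = FALSE], 2, cumsum)
    S1 <- apply(M1[L:1, , drop = FALSE], 2, cumsum)[L:1, , drop = FALSE]
    for (b in seq_len(L - 1)) {
      pb <- P0[b, ] + bulge_w[b] + S1[b + 1, ]
      upd <- which(pb < best[seq_len(n1)])
      if (length(upd)) {
        best[upd] <- pb[upd]
        bulge_at[upd] <- b
      }
    }
  }
  list(penalty = best, bulge_at = bulge_at, ungapped = pen0)
}

.alignment_string <- function(rc_code, target_code, start, bulge_at) {
  L <- length(rc_code)
  syms <- character(0)
  tpos <- start
  for (s in seq_len(L)) {
    cost <- .pair_cost[rc_code[s], target_code[tpos]]
    syms <- c(syms, if (cost == 0) "|" else if (cost == 0.5) "o" else "x")
    tpos <- tpos + 1
    if (!is.na(bulge_at) && s == bulge_at) {
      syms <- c(syms, "-")
      tpos <- tpos + 1
    }
  }
  paste(syms, collapse = "")
}

#' Scan transcripts for miRNA binding sites by complementarity penalty
#'
#' Slides the reverse complement of each mature miRNA along each target
#' transcript. At each offset the penalty is the weighted sum of mismatches
#' (1), G:U wobbles (0.5) and at most one single-nucleotide target bulge
#' (2), with weights doubled at miRNA positions 2--13 (the extended 5'
#' seed). Sites at or below `max_penalty` are reported, with the cleavage
#' position opposite miRNA positions 10--11. Scanning is performed against
#' the provided (stranded) transcript sequence only; ambiguous bases score
#' as mismatches.
#'
#' @param mirnas Named character vector of mature miRNA sequences
#'   (18--26 nt).
#' @param targets Named character vector of target transcript sequences.
#' @param max_penalty Report sites with penalty `<=` this (default 3).
#' @param allow_bulge Consider single-nucleotide target bulges (default
#'   TRUE).
#' @param best_only Keep only the best site per (miRNA, target) pair.
#' @return Tibble: `mirna`, `target`, `start`, `end` (1-based, inclusive,
#'   on the target), `penalty`, `cleavage` (target base paired with miRNA
#'   position 10), `alignment` (`|` match, `o` wobble, `x` mismatch, `-`
#'   bulge, 5'->3' on the target).
#' @export
scan_mirna_targets <- function(mirnas, targets, max_penalty = 3,
                               allow_bulge = TRUE, best_only = FALSE) {
  assert_dna(mirnas, "miRNA")
  assert_dna(targets, "target")
  if (any(nchar(mirnas) < 18 | nchar(mirnas) > 26))
    abort("mature miRNA length must be 18-26 nt")
  if (is.null(names(mirnas))) names(mirnas) <- paste0("miR", seq_along(mirnas))
  if (is.null(names(targets))) names(targets) <- paste0("t", seq_along(targets))
  rows <- list()
  tcodes <- lapply(targets, .base_code)
  for (mi in names(mirnas)) {
    L <- nchar(mirnas[[mi]])
    w_mirna <- ifelse(seq_len(L) %in% 2:13, 2, 1)
    w_site <- rev(w_mirna)                     # site pos s = miRNA pos L-s+1
    # bulge between site positions b and b+1 sits between miRNA positions
    # L-b and L-b+1; doubled when the 5'-ward flank (miRNA pos L-b) is in
    # the extended seed
    bulge_w <- 2 * ifelse((L - seq_len(L - 1)) %in% 2:13, 2, 1)
    rc_code <- .base_code(revcomp(mirnas[[mi]]))
    for (tg in names(targets)) {
      sc <- .scan_one(rc_code, tcodes[[tg]], w_site, bulge_w, allow_bulge)
      if (is.null(sc)) next
      hits <- which(sc$penalty <= max_penalty)
      if (best_only && length(hits) > 1)
        hits <- hits[which.min(sc$penalty[hits])]
      if (!length(hits)) next
      for (h in hits) {
        bl <- sc$bulge_at[h]
        site_len <- L + ifelse(is.na(bl), 0, 1)
        rows[[length(rows) + 1]] <- tibble(
          mirna = mi, target = tg, start = h, end = h + site_len - 1,
          penalty = sc$penalty[h],
          cleavage = h + (L - 10L),
          alignment = .alignment_string(rc_code, tcodes[[tg]], h, bl))
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble(mirna = character(0), target = character(0),
                  start = integer(0), end = integer(0),
                  penalty = numeric(0), cleavage = integer(0),
                  alignment = character(0))
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random Eulerian-walk shuffle that preserves the exact dinucleotide
#' composition (used to build negative controls for the site scanner).
#' Falls back to a plain shuffle, with a warning, if no valid walk is found
#' within `max_tries`.
#'
#' @param sequence A single DNA string.
#' @param max_tries Attempts at a valid Eulerian ordering.
#' @return A shuffled string of identical length and dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(sequence, max_tries = 50) {
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 3) return(sequence)
  edges <- split(ch[-1], ch[-n])        # per-source lists of next letters
  for (try in seq_len(max_tries)) {
    shuf <- lapply(edges, sample)
    ptr <- lapply(shuf, function(x) 1L)
    out <- character(n)
    out[1] <- ch[1]
    cur <- ch[1]
    ok <- TRUE
    for (i in 2:n) {
      k <- ptr[[cur]]
      if (is.null(shuf[[cur]]) || k > length(shuf[[cur]])) { ok <- FALSE; break }
      nxt <- shuf[[cur]][k]
      ptr[[cur]] <- k + 1L
      out[i] <- nxt
      cur <- nxt
    }
    # a completed walk has consumed all n-1 edges, so it is a valid shuffle
    if (ok) return(paste(out, collapse = ""))
  }
  warn("dinucleotide shuffle failed; falling back to plain shuffle")
  paste(sample(ch), collapse = "")
}
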