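# Competing-endogenous-RNA network construction: precursor-homology
# exclusion, triplet assembly (lncRNA decoy -- miRNA core -- mRNA target
# sharing a binding site), and network export.

#' Exclude lncRNAs that look like miRNA precursors
#'
#' Removes any lncRNA containing an ungapped local match to a precursor
#' hairpin at `identity_min` identity or better over a window of
#' `match_len` nt, found by exact k-mer seeding and diagonal extension.
#'
#' @param lncrnas Named character vector of lncRNA sequences.
#' @param precursors Named character vector of hairpin sequences (may be
#'   empty).
#' @param identity_min Identity threshold (default 0.90).
#' @param match_len Window length in nt (default 50).
#' @param k Seed k-mer size; the default 8 guarantees a seed exists for any
#'   qualifying window at the default thresholds.
#' @return The filtered vector; removed entries are recorded in the
#'   `"removed"` attribute (tibble `lncrna`, `precursor`).
#' @export
exclude_precursor_lncrnas <- function(lncrnas, precursors,
                                      identity_min = 0.90, match_len = 50,
                                      k = 8) {
  if (length(precursors) == 0) {
    attr(lncrnas, "removed") <- tibble(lncrna = character(0),
                                       precursor = character(0))
    return(lncrnas)
  }
  removed <- list()
  for (li in names(lncrnas) %||% seq_along(lncrnas)) {
    lseq <- seq_chars(lncrnas[[li]])
    # k-mer index of the lncRNA
    nL <- length(lseq)
    if (nL < match_len) next
    lk <- vapply(seq_len(nL - k + 1),
                 function(i) paste(lseq[i:(i + k - 1)], collapse = ""),
                 character(1))
    lk_idx <- split(seq_along(lk), lk)
    for (pi in names(precursors) %||% seq_along(precursors)) {
      pseq <- seq_chars(precursors[[pi]])
      nP <- length(pseq)
      if (nP < match_len) next
      win <- match_len
      diags <- integer(0)
      for (j in seq_len(nP - k + 1)) {
        km <- paste(pseq[j:(j + k - 1)], collapse = "")
        hit <- lk_idx[[km]]
        if (!is.null(hit)) diags <- c(diags, hit - j)
      }
      found <- FALSE
      for (d in unique(diags)) {
        # overlap of the two sequences on diagonal d (lpos = ppos + d)
        p_lo <- max(1, 1 - d); p_hi <- min(nP, nL - d)
        len <- p_hi - p_lo + 1
        if (len < win) next
        mvec <- lseq[(p_lo:p_hi) + d] == pseq[p_lo:p_hi]
        cs <- cumsum(c(0, mvec))
        wid <- cs[(win + 1):(len + 1)] - cs[1:(len - win + 1)]
        if (any(wid / win >= identity_min)) { found <- TRUE; break }
      }
      if (found) {
        removed[[length(removed) + 1]] <- tibble(lncrna = li, precursor = pi)
        break
      }
    }
  }
  removed <- bind_rows(removed)
  if (nrow(removed) == 0)
    removed <- tibble(lncrna = character(0), precursor = character(0))
  out <- lncrnas[!(names(lncrnas) %||% seq_along(lncrnas)) %in% removed$lncrna]
  attr(out, "removed") <- removed
  out
}

#' Assemble ceRNA triplets (lncRNA decoy, miRNA core, mRNA target)
#'
#' Emits (L, M, G) whenever miRNA M has a reported binding site in both
#' lncRNA L and mRNA G, L and G are differentially expressed, and their
#' expression correlation reaches `r_min`. The `direction_consistent` flag
#' marks triplets where L and G change in the same direction and, if M is
#' differentially expressed, M changes in the opposite direction.
#'
#' @param de_lncrnas,de_mrnas Differential-expression tibbles (columns
#'   `transcript`, `log2fc`) holding the significant lncRNAs and mRNAs.
#' @param de_mirnas Same for miRNAs; used when `require_mirna_de` is TRUE
#'   and for the direction flag.
#' @param lnc_sites,mrna_sites [scan_mirna_targets()] results against the
#'   lncRNAs and the mRNAs.
#' @param expression An [expression_matrix()] covering lncRNAs and mRNAs.
#' @param r_min Correlation threshold on log2(abundance + 1) (default
#'   0.95).
#' @param require_mirna_de Keep only triplets whose miRNA is itself
#'   differentially expressed (default TRUE).
#' @return Tibble: `lncrna`, `mirna`, `mrna`, `lnc_penalty`, `lnc_start`,
#'   `mrna_penalty`, `mrna_start`, `pearson_r`, `direction_consistent`.
#' @export
build_triplets <- function(de_lncrnas, de_mrnas, de_mirnas, lnc_sites,
                           mrna_sites, expression, r_min = 0.95,
                           require_mirna_de = TRUE) {
  empty <- tibble(lncrna = character(0), mirna = character(0),
                  mrna = character(0), lnc_penalty = numeric(0),
                  lnc_start = integer(0), mrna_penalty = numeric(0),
                  mrna_start = integer(0), pearson_r = numeric(0),
                  direction_consistent = logical(0))
  ls <- lnc_sites |> filter(.data$target %in% de_lncrnas$transcript) |>
    group_by(.data$mirna, .data$target) |>
    slice_min(.data$penalty, n = 1, with_ties = FALSE) |> ungroup() |>
    select("mirna", lncrna = "target", lnc_penalty = "penalty",
           lnc_start = "start")
  ms <- mrna_sites |> filter(.data$target %in% de_mrnas$transcript) |>
    group_by(.data$mirna, .data$target) |>
    slice_min(.data$penalty, n = 1, with_ties = FALSE) |> ungroup() |>
    select("mirna", mrna = "target", mrna_penalty = "penalty",
           mrna_start = "start")
  if (require_mirna_de) {
    ls <- ls |> filter(.data$mirna %in% de_mirnas$transcript)
    ms <- ms |> filter(.data$mirna %in% de_mirnas$transcript)
  }
  tri <- inner_join(ls, ms, by = "mirna", relationship = "many-to-many")
  if (nrow(tri) == 0) return(empty)
  miss <- setdiff(unique(c(tri$lncrna, tri$mrna)),
                  rownames(expression$values))
  if (length(miss)) abort("inconsistent inputs: missing expression rows")
  corr <- .expr_correlator(expression, unique(tri$lncrna), unique(tri$mrna))
  tri$pearson_r <- corr(tri$lncrna, tri$mrna)
  tri <- tri |> filter(.data$pearson_r >= r_min)
  if (nrow(tri) == 0) return(empty)
  lfc_l <- setNames(de_lncrnas$log2fc, de_lncrnas$transcript)
  lfc_g <- setNames(de_mrnas$log2fc, de_mrnas$transcript)
  lfc_m <- setNames(de_mirnas$log2fc, de_mirnas$transcript)
  tri |> mutate(
    direction_consistent =
      sign(lfc_l[.data$lncrna]) == sign(lfc_g[.data$mrna]) &
      (!.data$mirna %in% names(lfc_m) |
         sign(lfc_m[.data$mirna]) != sign(lfc_g[.data$mrna]))) |>
    select("lncrna", "mirna", "mrna", "lnc_penalty", "lnc_start",
           "mrna_penalty", "mrna_start", "pearson_r",
           "direction_consistent") |>
    arrange(.data$mirna, .data$lncrna, .data$mrna)
}

#' Build a typed ceRNA network from triplets
#'
#' Nodes are typed lncRNA/miRNA/mRNA; edges are miRNA->lncRNA sequestration,
#' miRNA->mRNA repression, and lncRNA--mRNA co-expression, deduplicated and
#' carrying their evidence (site penalty or correlation). The network
#' decomposes into miRNA-centered stars.
#'
#' @param triplets A [build_triplets()] result.
#' @param tissue Optional tissue label attached to the network.
#' @return Object of class `cerna_network`: list with `nodes`, `edges`
#'   tibbles and an igraph `graph`.
#' @export
cerna_network <- function(triplets, tissue = NA_character_) {
  nodes <- bind_rows(
    tibble(id = unique(triplets$lncrna), type = "lncRNA"),
    tibble(id = unique(triplets$mirna), type = "miRNA"),
    tibble(id = unique(triplets$mrna), type = "mRNA")) |>
    arrange(.data$type, .data$id)
  edges <- bind_rows(
    triplets |> distinct(.data$mirna, .data$lncrna, .data$lnc_penalty) |>
      transmute(from = .data$mirna, to = .data$lncrna,
                edge_type = "sequestration", evidence = .data$lnc_penalty),
    triplets |> distinct(.data$mirna, .data$mrna, .data$mrna_penalty) |>
      transmute(from = .data$mirna, to = .data$mrna,
                edge_type = "repression", evidence = .data$mrna_penalty),
    triplets |> distinct(.data$lncrna, .data$mrna, .data$pearson_r) |>
      transmute(from = .data$lncrna, to = .data$mrna,
                edge_type = "coexpression", evidence = .data$pearson_r)) |>
    distinct(.data$from, .data$to, .data$edge_type, .keep_all = TRUE) |>
    arrange(.data$edge_type, .data$from, .data$to)
  g <- if (nrow(nodes) > 0)
    igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  else igraph::make_empty_graph(directed = FALSE)
  structure(list(nodes = nodes, edges = edges, graph = g, tissue = tissue),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network> %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(table(x$nodes$type), names(table(x$nodes$type)),
                    collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Write / read a ceRNA network edge list
#'
#' Tab-separated edge list with typed endpoints and evidence columns;
#' deterministic ordering. [read_network()] reconstructs the
#' `cerna_network`; [triplets_from_network()] recovers the triplet set
#' (lncRNA and mRNA of the same miRNA joined by a co-expression edge).
#'
#' @param network A [cerna_network()].
#' @param path Output TSV path.
#' @return `write_network()` the path, invisibly; `read_network()` a
#'   `cerna_network`; `triplets_from_network()` a tibble of triplets.
#' @export
write_network <- function(network, path) {
  types <- setNames(network$nodes$type, network$nodes$id)
  out <- network$edges |>
    mutate(from_type = unname(types[.data$from]),
           to_type = unname(types[.data$to]))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  ed <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          from = "c", to = "c", edge_type = "c",
                          evidence = "d", from_type = "c", to_type = "c"))
  nodes <- bind_rows(
    ed |> select(id = "from", type = "from_type"),
    ed |> select(id = "to", type = "to_type")) |>
    distinct() |> arrange(.data$type, .data$id)
  edges <- ed |> select("from", "to", "edge_type", "evidence") |>
    arrange(.data$edge_type, .data$from, .data$to)
  g <- if (nrow(nodes) > 0)
    igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  else igraph::make_empty_graph(directed = FALSE)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 tissue = NA_character_), class = "cerna_network")
}

#' @rdname write_network
#' @export
triplets_from_network <- function(network) {
  seq_e <- network$edges |> filter(.data$edge_type == "sequestration")
  rep_e <- network$edges |> filter(.data$edge_type == "repression")
  coex <- network$edges |> filter(.data$edge_type == "coexpression")
  tri <- inner_join(seq_e |> select(mirna = "from", lncrna = "to",
                                    lnc_penalty = "evidence"),
                    rep_e |> select(mirna = "from", mrna = "to",
                                    mrna_penalty = "evidence"),
                    by = "mirna", relationship = "many-to-many")
  semi_join(tri,
            coex |> select(lncrna = "from", mrna = "to"),
            by = c("lncrna", "mrna")) |>
    mutate(pearson_r = {
      key <- paste(.data$lncrna, .data$mrna)
      ev <- setNames(coex$evidence, paste(coex$from, coex$to))
      unname(ev[key])
    }) |>
    arrange(.data$mirna, .data$lncrna, .data$mrna)
}

#' Plot a ceRNA network
#'
#' miRNA-centered star layout via igraph; node shape/colour by type.
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cerna_network <- function(object, ...) {
  if (nrow(object$nodes) == 0)
    return(ggplot2::ggplot() + ggplot2::theme_void())
  lay <- igraph::layout_with_fr(object$graph)
  pos <- tibble(id = object$nodes$id, x = lay[, 1], y = lay[, 2],
                type = object$nodes$type)
  ed <- object$edges |>
    left_join(pos |> select("id", x1 = "x", y1 = "y"),
              by = c(from = "id")) |>
    left_join(pos |> select("id", x2 = "x", y2 = "y"), by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2,
                                       linetype = .data$edge_type),
                          colour = "grey60") +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$type,
                                     shape = .data$type), size = 3) +
    ggplot2::theme_void()
}
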