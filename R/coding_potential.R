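# Coding-potential heuristics for the identification cascade: a longest-ORF
# rule and the Fickett TESTCODE position/composition statistic. The two
# independent signals reproduce the two-tool structure (discordant calls
# define transcripts of uncertain coding potential, TUCP).

# ---- ORF scan ---------------------------------------------------------------

.codon_split <- function(chars, frame) {
  n <- length(chars)
  m <- (n - frame) %/% 3
  if (m < 1) return(character(0))
  idx <- frame + 1 + 3 * (seq_len(m) - 1)
  paste0(chars[idx], chars[idx + 1], chars[idx + 2])
}

.longest_orf1 <- function(s) {
  ch <- seq_chars(s)
  best <- 0L
  for (f in 0:2) {
    cods <- .codon_split(ch, f)
    if (length(cods) < 2) next
    starts <- which(cods == "ATG")
    stops <- which(cods %in% c("TAA", "TAG", "TGA"))
    if (!length(starts) || !length(stops)) next
    # for each start, the next in-frame stop
    nxt <- stops[findInterval(starts, stops) + 1L]
    len <- nxt - starts
    len <- len[!is.na(len)]
    if (length(len)) best <- max(best, max(len))
  }
  best
}

#' Longest open reading frame, in codons
#'
#' Scans the three forward frames of the transcript sequence for ATG-to-stop
#' open reading frames (transcripts are stranded, so the reverse strand is
#' never scanned). The length counts codons from ATG up to, but excluding,
#' the stop codon; ORFs without an in-frame stop are not counted.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Integer vector of maximal ORF lengths (codons), 0 if none.
#' @export
longest_orf <- function(sequence) {
  assert_dna(sequence)
  vapply(sequence, .longest_orf1, integer(1), USE.NAMES = FALSE)
}

# ---- Fickett TESTCODE -------------------------------------------------------

# Standard published lookup tables (Fickett 1982): probability that a
# sequence with the given position/composition parameter is coding, and the
# per-base weights. Stored in ascending threshold order for findInterval().
.fk_pos_thr <- c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9)
.fk_pos_prob <- list(
  A = rev(c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22)),
  C = rev(c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23)),
  G = rev(c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08)),
  T = rev(c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)))
.fk_pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fk_cont_thr <- c(0.17, 0.19, 0.21, 0.23, 0.25, 0.27, 0.29, 0.31, 0.33)
.fk_cont_prob <- list(
  A = rev(c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21)),
  C = rev(c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31)),
  G = rev(c(0.40, 0.54, 0.47, 0.64, 0.61, 0.42, 0.41, 0.41, 0.33, 0.29)),
  T = rev(c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)))
.fk_cont_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

.fickett1 <- function(s) {
  ch <- seq_chars(s)
  n <- length(ch)
  if (n < 3) return(0)
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    hits <- ch == b
    c1 <- sum(hits[seq(1, n, by = 3)])
    c2 <- sum(hits[seq(2, n, by = 3)])
    c3 <- if (n >= 3) sum(hits[seq(3, n, by = 3)]) else 0
    posval <- max(c1, c2, c3) / (min(c1, c2, c3) + 1)
    contval <- (c1 + c2 + c3) / n
    pi <- findInterval(posval, .fk_pos_thr) + 1L
    ci <- findInterval(contval, .fk_cont_thr) + 1L
    score <- score + .fk_pos_prob[[b]][pi] * .fk_pos_w[[b]] +
      .fk_cont_prob[[b]][ci] * .fk_cont_w[[b]]
  }
  score
}

#' Fickett TESTCODE score
#'
#' Position-dependent base composition statistic: for each base, the
#' asymmetry of its usage across the three codon positions and its overall
#' fraction are converted to coding probabilities through the standard
#' published lookup tables and combined with the standard weights. Higher
#' scores indicate protein-coding-like composition.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Numeric vector of scores (roughly 0.2--1.3).
#' @export
fickett_score <- function(sequence) {
  assert_dna(sequence)
  vapply(sequence, .fickett1, numeric(1), USE.NAMES = FALSE)
}

#' Call coding potential by two independent heuristics
#'
#' The ORF rule calls a transcript coding when its longest forward-frame
#' ATG-to-stop ORF reaches `orf_codons` codons (default 100). The
#' composition rule calls it coding when the Fickett TESTCODE score reaches
#' `fickett_threshold` (default 0.95). Discordance between the two calls is
#' what defines a TUCP downstream.
#'
#' @param sequence Named character vector of transcript sequences.
#' @param orf_codons ORF length threshold in codons.
#' @param fickett_threshold TESTCODE score threshold.
#' @return Tibble with columns `id`, `length`, `orf_codons`, `orf_call`,
#'   `fickett_score`, `composition_call` (calls are `"coding"`/`"noncoding"`).
#' @export
call_coding_potential <- function(sequence, orf_codons = 100,
                                  fickett_threshold = 0.95) {
  assert_dna(sequence)
  if (any(nchar(sequence) < 1)) abort("empty sequence")
  ids <- names(sequence) %||% paste0("seq", seq_along(sequence))
  orf <- longest_orf(sequence)
  fk <- fickett_score(sequence)
  orf_call <- ifelse(orf >= orf_codons, "coding", "noncoding")
  comp_call <- ifelse(fk >= fickett_threshold, "coding", "noncoding")
  tibble(id = ids,
         length = nchar(sequence),
         orf_codons = orf,
         orf_call = orf_call,
         fickett_score = fk,
         composition_call = comp_call)
}

# ---- sequence construction helpers used by the simulator -------------------

# Codon pool with strongly position-biased composition so planted coding
# sequences score high on both heuristics. Stop codons excluded.
.coding_codon_pool <- local({
  p1 <- c(A = 0.35, C = 0.15, G = 0.45, T = 0.05)
  p2 <- c(A = 0.40, C = 0.30, G = 0.10, T = 0.20)
  p3 <- c(A = 0.10, C = 0.35, G = 0.45, T = 0.10)
  cods <- expand.grid(b1 = names(p1), b2 = names(p2), b3 = names(p3),
                      stringsAsFactors = FALSE)
  cods$codon <- paste0(cods$b1, cods$b2, cods$b3)
  cods$w <- p1[cods$b1] * p2[cods$b2] * p3[cods$b3]
  keep <- !cods$codon %in% c("TAA", "TAG", "TGA")
  list(codon = cods$codon[keep], w = cods$w[keep] / sum(cods$w[keep]))
})

# A protein-coding-like ORF: ATG + biased codons + TAA.
coding_orf <- function(n_codons) {
  body <- sample(.coding_codon_pool$codon, n_codons - 1, replace = TRUE,
                 prob = .coding_codon_pool$w)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# Break every ORF of >= max_codons codons by replacing its middle codon with
# a stop; iterate to a fixpoint (inserting TAA can never create a new ATG).
strip_long_orfs <- function(s, max_codons = 59, max_iter = 50) {
  for (i in seq_len(max_iter)) {
    ch <- seq_chars(s)
    changed <- FALSE
    for (f in 0:2) {
      cods <- .codon_split(ch, f)
      if (length(cods) < 2) next
      starts <- which(cods == "ATG")
      stops <- which(cods %in% c("TAA", "TAG", "TGA"))
      if (!length(starts)) next
      nxt <- if (length(stops)) stops[findInterval(starts, stops) + 1L]
             else rep(NA_integer_, length(starts))
      # also break long stop-less runs at the tail
      lens <- ifelse(is.na(nxt), length(cods) + 1L - starts, nxt - starts)
      long <- which(lens >= max_codons)
      if (length(long)) {
        a <- starts[long[1]]
        mid <- a + lens[long[1]] %/% 2
        pos <- f + 1 + 3 * (mid - 1)
        substr(s, pos, pos + 2) <- "TAA"
        changed <- TRUE
        break
      }
    }
    if (!changed) return(s)
  }
  s
}

# A noncoding-like sequence: random, no ORF >= 60 codons, Fickett below the
# default threshold with margin.
noncoding_seq <- function(len, max_tries = 25) {
  for (i in seq_len(max_tries)) {
    s <- strip_long_orfs(random_dna(len))
    if (fickett_score(s) < 0.90 && longest_orf(s) < 60) return(s)
  }
  abort("failed to generate a noncoding-like sequence")
}

# A decoy transcript: short UTRs around a long, composition-biased ORF, so
# both coding-potential rules flag it and the cascade rejects it.
coding_decoy_seq <- function(len, min_codons = 120, max_tries = 50) {
  if (len < min_codons * 3 + 9) abort("decoy transcript too short for its ORF")
  n_cod <- max(min_codons, (len - 30) %/% 3)
  for (i in seq_len(max_tries)) {
    orf <- coding_orf(n_cod)
    utr_total <- len - nchar(orf)
    u5 <- utr_total %/% 2
    s <- paste0(if (u5 > 0) strip_long_orfs(random_dna(u5)) else "", orf,
                if (utr_total - u5 > 0) strip_long_orfs(random_dna(utr_total - u5)) else "")
    if (fickett_score(s) >= 0.97 && longest_orf(s) >= 100) return(s)
  }
  abort("failed to generate a coding decoy sequence")
}
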