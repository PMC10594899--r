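SEED_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "alignment-only")

# Vectorized seed scan of one miRNA against many UTRs. Returns a data.frame
# (utr_idx, start, end, class), 0-based half-open site coordinates.
seed_scan <- function(m, utrs) {
  if (nchar(m) < 8) stop("miRNA shorter than 8 nt has no full seed")
  comp <- function(x) chartr("ACGU", "UGCA", x)
  rc7 <- rc_rna(substr(m, 2, 8))
  rc6 <- rc_rna(substr(m, 2, 7))
  comp_m8 <- comp(substr(m, 8, 8))

  # zero-width lookahead so overlapping occurrences are all reported
  g7 <- gregexpr(paste0("(?=", rc7, ")"), utrs, perl = TRUE)
  g6 <- gregexpr(paste0("(?=", rc6, ")"), utrs, perl = TRUE)
  idx <- starts <- ends <- integer(0)
  cls <- character(0)
  for (j in seq_along(utrs)) {
    p7 <- g7[[j]]; p6 <- g6[[j]]
    has7 <- p7[1L] != -1L; has6 <- p6[1L] != -1L
    if (!has7 && !has6) next
    u <- utrs[[j]]; len <- nchar(u)
    if (has7) {
      p <- as.integer(p7)
      a1 <- p + 7L <= len & substring(u, p + 7L, p + 7L) == "A"
      idx <- c(idx, rep.int(j, length(p)))
      starts <- c(starts, p - 1L)
      ends <- c(ends, ifelse(a1, p + 7L, p + 6L))
      cls <- c(cls, ifelse(a1, "8mer", "7mer-m8"))
    }
    if (has6) {
      q <- as.integer(p6)
      # drop matches already covered by the nt 2-8 scan (comp(m8) just 5' of
      # the core on the UTR)
      ext <- q > 1L & substring(u, q - 1L, q - 1L) == comp_m8
      q <- q[!ext]
      if (length(q) > 0) {
        a1 <- q + 6L <= len & substring(u, q + 6L, q + 6L) == "A"
        idx <- c(idx, rep.int(j, length(q)))
        starts <- c(starts, q - 1L)
        ends <- c(ends, ifelse(a1, q + 6L, q + 5L))
        cls <- c(cls, ifelse(a1, "7mer-A1", "6mer"))
      }
    }
  }
  out <- data.frame(utr_idx = idx, start = starts, end = ends, class = cls,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$utr_idx, out$start, out$end), , drop = FALSE]
}

#' Scan a 3'UTR for canonical seed-match sites of one miRNA
#'
#' The seed is miRNA nucleotides 2-8 counted from the 5' end. A site is
#' classified by Watson-Crick complementarity between the UTR and the seed,
#' read 5'->3' on the UTR (the reverse complement of the seed appears in the
#' UTR, followed 3'-ward on the UTR by the base opposite miRNA position 1):
#' 8mer = match to nt 2-8 plus an A opposite nt 1; 7mer-m8 = match to nt 2-8;
#' 7mer-A1 = match to nt 2-7 plus the A; 6mer = match to nt 2-7. Each
#' distinct site is reported once with its highest class.
#'
#' @param mirna_seq mature miRNA sequence, 5'->3' (RNA; T accepted).
#' @param utr_seq 3'UTR sequence, 5'->3'.
#' @return data.frame with `start`, `end` (0-based half-open on the UTR; the
#'   A1 position is included for 8mer and 7mer-A1 sites) and `class`.
#' @export
find_seed_sites <- function(mirna_seq, utr_seq) {
  hits <- seed_scan(as_rna(mirna_seq), as_rna(utr_seq))
  out <- hits[, c("start", "end", "class")]
  rownames(out) <- NULL
  out
}

#' Score a miRNA:UTR-window duplex by local alignment
#'
#' Smith-Waterman local alignment (affine gaps) of the reversed miRNA against
#' the window, so pairing is antiparallel. Substitution scores: Watson-Crick
#' pair `match` (+5), G:U wobble `wobble` (+2), mismatch (-3); gap open -8,
#' gap extend -2. Pairing scores at miRNA seed positions 2-8 are multiplied
#' by `seed_scale` (default 4, the scale parameter miRanda applies to its 5'
#' seed region), so a perfect full-length complement of a 22-mer scores
#' 15*5 + 7*20 = 215 and clears the conventional `score > 150` filter.
#'
#' @param mirna_seq mature miRNA, 5'->3'.
#' @param utr_window UTR window sequence, 5'->3'.
#' @param match,wobble,mismatch,gap_open,gap_extend scoring constants.
#' @param seed_scale multiplier on pairing scores at miRNA positions 2-8.
#' @return List with `score` and `pairing`, a data.frame (`mirna_pos`
#'   1-based from the miRNA 5' end, `window_pos` 1-based on the window,
#'   `type` in GC/AU/GU/MM) ordered 5'->3' along the window.
#' @export
align_duplex <- function(mirna_seq, utr_window, match = 5, wobble = 2,
                         mismatch = -3, gap_open = 8, gap_extend = 2,
                         seed_scale = 4) {
  res <- .duplex_align_cpp(as_rna(mirna_seq), as_rna(utr_window),
                           match, wobble, mismatch, gap_open, gap_extend,
                           seed_scale, 2L, 8L)
  pairs <- res$pairs
  type <- c("MM", "GU", "AU", "GC")[pairs[, 3L] + 1L]
  list(score = res$score,
       pairing = data.frame(mirna_pos = pairs[, 1L],
                            window_pos = pairs[, 2L],
                            type = type, stringsAsFactors = FALSE))
}

# Stack-energy sum from the raw pairs matrix of .duplex_align_cpp
# (codes: 0 mismatch, 1 G:U, 2 A:U, 3 G:C).
energy_from_pairs <- function(pairs) {
  code <- pairs[, 3L]
  keep <- code > 0L
  if (sum(keep) < 2L) return(0)
  wp <- pairs[keep, 2L]; mp <- pairs[keep, 1L]; code <- code[keep]
  o <- order(wp)
  wp <- wp[o]; mp <- mp[o]; code <- code[o]
  n <- length(wp)
  adj <- wp[-1L] == wp[-n] + 1L & mp[-1L] == mp[-n] - 1L
  gc1 <- code[-n] == 3L; gc2 <- code[-1L] == 3L
  terms <- ifelse(gc1 & gc2, -3, ifelse(!gc1 & !gc2, -1, -2))
  sum(terms[adj])
}

#' Stacking-energy proxy of a duplex pairing
#'
#' Sums a term over every stack (two paired positions adjacent in both
#' strands): -3.0 kcal/mol when both pairs are G:C, -1.0 when both are
#' A:U or G:U, -2.0 for a mixed stack. Mismatched (unpaired) positions
#' contribute nothing and interrupt stacking.
#'
#' @param pairing data.frame from [align_duplex()].
#' @return Energy proxy in kcal/mol (<= 0).
#' @export
duplex_energy <- function(pairing) {
  code <- match(pairing$type, c("MM", "GU", "AU", "GC")) - 1L
  energy_from_pairs(cbind(pairing$mirna_pos, pairing$window_pos, code))
}

#' Predict miRNA targets over a set of 3'UTRs
#'
#' Candidate sites are found by the seed scanner ([find_seed_sites()]); each
#' site's surrounding window (extended 5'-ward on the UTR to accommodate the
#' miRNA 3' region) is re-scored by [align_duplex()] and [duplex_energy()].
#' A site is reported iff `score > score_min` and `energy < energy_max`
#' (both strict). Per (miRNA, gene) pair the best-scoring site carries
#' `best = TRUE`.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param utrs named character vector of 3'UTR sequences (names = gene ids).
#' @param score_min alignment-score threshold, strict (default 150).
#' @param energy_max energy threshold in kcal/mol, strict (default -20).
#' @param ... scoring constants passed to [align_duplex()].
#' @return data.frame of TargetHit rows: `mirna_id`, `gene_id`, `start`,
#'   `end`, `class`, `score`, `energy`, `best`.
#' @export
predict_targets <- function(mirnas, utrs, score_min = 150, energy_max = -20,
                            ...) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(utrs)))
  utrs_rna <- as_rna(unname(utrs))
  utr_len <- nchar(utrs_rna)
  dots <- list(...)
  arg <- function(nm, dflt) dots[[nm]] %||% dflt
  rows <- vector("list", length(mirnas))
  for (mi in seq_along(mirnas)) {
    m <- as_rna(mirnas[[mi]])
    lm <- nchar(m)
    sites <- seed_scan(m, utrs_rna)
    if (nrow(sites) == 0) next
    keep <- logical(nrow(sites))
    score <- energy <- numeric(nrow(sites))
    for (r in seq_len(nrow(sites))) {
      j <- sites$utr_idx[r]
      w_from <- max(1L, sites$start[r] + 1L - (lm - 6L) - 4L)
      w_to <- min(utr_len[j], sites$end[r] + 2L)
      aln <- .duplex_align_cpp(m, substr(utrs_rna[j], w_from, w_to),
                               arg("match", 5), arg("wobble", 2),
                               arg("mismatch", -3), arg("gap_open", 8),
                               arg("gap_extend", 2), arg("seed_scale", 4),
                               2L, 8L)
      e <- energy_from_pairs(aln$pairs)
      keep[r] <- aln$score > score_min && e < energy_max
      score[r] <- aln$score; energy[r] <- e
    }
    if (!any(keep)) next
    sk <- sites[keep, , drop = FALSE]
    rows[[mi]] <- data.frame(
      mirna_id = names(mirnas)[mi], gene_id = names(utrs)[sk$utr_idx],
      start = sk$start, end = sk$end, class = sk$class,
      score = score[keep], energy = energy[keep],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      start = integer(0), end = integer(0),
                      class = character(0), score = numeric(0),
                      energy = numeric(0), best = logical(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  # flag the best-scoring site per (miRNA, gene) pair; ties: leftmost site
  o <- order(hits$mirna_id, hits$gene_id, -hits$score, hits$start)
  key <- paste(hits$mirna_id, hits$gene_id, sep = "\r")[o]
  best_rows <- o[!duplicated(key)]
  hits$best <- FALSE
  hits$best[best_rows] <- TRUE
  rownames(hits) <- NULL
  hits
}

#' Intersect two target-prediction tables on (miRNA, gene) pairs
#'
#' Keeps the rows of `hits_a` whose (miRNA, gene) pair also occurs in
#' `hits_b` — the workflow step that intersects one predictor's filtered
#' hits with a second predictor's calls.
#'
#' @param hits_a,hits_b data.frames with `mirna_id` and `gene_id` columns.
#' @return The filtered `hits_a`.
#' @export
intersect_predictions <- function(hits_a, hits_b) {
  key <- function(h) paste(h$mirna_id, h$gene_id, sep = "\r")
  out <- hits_a[key(hits_a) %in% key(hits_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
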