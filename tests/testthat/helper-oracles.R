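# Independent oracles used to cross-check package implementations. These are
# deliberately written as plain, slow, literal translations of the
# definitions, sharing no code with the package internals.

RNA <- c("A", "C", "G", "U")
COMP <- c(A = "U", C = "G", G = "C", U = "A")

rand_rna <- function(len) paste(sample(RNA, len, replace = TRUE), collapse = "")

# median-of-ratios, re-derived literally from its definition
oracle_size_factors <- function(counts) {
  ok <- apply(counts > 0, 1, all)
  gm <- apply(counts[ok, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  apply(counts[ok, , drop = FALSE], 2, function(col) median(col / gm))
}

# hypergeometric upper tail P(X >= k) by exhaustive enumeration of draws
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)              # items 1..K are "inside"
  hits <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(hits >= k)
}

# brute-force seed-site scan: test every UTR offset against the literal
# class definitions (complementarity checked base by base)
oracle_seed_scan <- function(m, u) {
  mv <- strsplit(m, "")[[1]]
  uv <- strsplit(u, "")[[1]]
  lu <- length(uv)
  res <- list()
  is_comp <- function(ui, mj) uv[ui] == COMP[[mv[mj]]]
  for (i in seq_len(lu)) {
    # core6 at i..i+5 pairing m7..m2
    if (i + 5 > lu) next
    core6 <- all(vapply(0:5, function(o) is_comp(i + o, 7 - o), logical(1)))
    if (!core6) next
    m8 <- i > 1 && is_comp(i - 1, 8)
    if (m8) {
      a1 <- i + 6 <= lu && uv[i + 6] == "A"
      res[[length(res) + 1]] <- data.frame(
        start = i - 2L, end = if (a1) i + 6L else i + 5L,
        class = if (a1) "8mer" else "7mer-m8", stringsAsFactors = FALSE)
    } else {
      a1 <- i + 6 <= lu && uv[i + 6] == "A"
      res[[length(res) + 1]] <- data.frame(
        start = i - 1L, end = if (a1) i + 6L else i + 5L,
        class = if (a1) "7mer-A1" else "6mer", stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, res))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# independent quadratic-space affine-gap local aligner (score only), same
# scoring specification as align_duplex but a separate literal implementation
oracle_align_score <- function(mirna, window, match = 5, wobble = 2,
                               mismatch = -3, gap_open = 8, gap_extend = 2,
                               seed_scale = 4) {
  r <- rev(strsplit(mirna, "")[[1]])
  w <- strsplit(window, "")[[1]]
  lm <- length(r); lw <- length(w)
  if (lm == 0 || lw == 0) return(0)
  sub_score <- function(i, j) {
    a <- r[i]; b <- w[j]
    pc <- if (COMP[[a]] == b) match
          else if ((a == "G" && b == "U") || (a == "U" && b == "G")) wobble
          else mismatch
    orig <- lm - i + 1
    if (orig >= 2 && orig <= 8) pc * seed_scale else pc
  }
  NEG <- -1e9
  M <- matrix(0, lm + 1, lw + 1)
  X <- matrix(NEG, lm + 1, lw + 1)
  Y <- matrix(NEG, lm + 1, lw + 1)
  best <- 0
  for (i in 2:(lm + 1)) {
    for (j in 2:(lw + 1)) {
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + sub_score(i - 1, j - 1))
      X[i, j] <- max(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# default simulation scaled down for fast unit tests
small_sim <- function(seed = 1L, ...) {
  sim_config(n_chroms = 6, n_mirnas_total = 60, locus_chrom = "chr3",
             locus_interval = c(1e5, 3e5), n_locus_mirnas = 30,
             n_up_planted = 10, n_down_planted = 12, n_genes = 60,
             n_pathways = 10, geneset_size_range = c(5, 15),
             n_reads = 5000, seed = seed, ...)
}
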