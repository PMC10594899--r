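#' Derive a child RNG seed from a root seed and a stream label
#'
#' Every stochastic operation in the package draws its randomness from a
#' stream seed derived deterministically from one root seed plus the
#' operation's name. This lets individual simulation stages be re-run in
#' isolation while staying byte-identical to a full pipeline run.
#'
#' The derivation hashes the label with a djb2-style rolling hash, mixes it
#' into the seed by XOR, and scrambles once with a Lehmer step modulo
#' 2^31 - 1, so the result is always a valid positive 32-bit integer seed.
#'
#' @param seed integer root seed.
#' @param label character stream label (usually the operation name).
#' @return A positive integer seed strictly below 2^31 - 1.
#' @export
#' @examples
#' derive_seed(1L, "simulate_counts")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 5381
  for (ch in utf8ToInt(label)) h <- (h * 33 + ch) %% 2147483647
  x <- bitwXor(as.integer(seed %% 2147483647), as.integer(h))
  x <- x %% 2147483647L
  if (x <= 0L) x <- x + 2147483646L
  as.integer((as.numeric(x) * 16807) %% 2147483647)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- sequence helpers (canonical internal alphabet is RNA: A C G U) -------

# Coerce to uppercase RNA; T is accepted on input and mapped to U.
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

rc_rna <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(chartr("ACGU", "UGCA", as_rna(s)), "")[[1L]])
    paste0(chars, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

random_rna <- function(n, len, first_u_prob = NA) {
  vapply(seq_len(n), function(i) {
    l <- if (length(len) > 1L) sample(len, 1L) else len
    first <- if (!is.na(first_u_prob)) {
      if (runif(1) < first_u_prob) "U" else sample(c("A", "C", "G"), 1L)
    } else sample(c("A", "C", "G", "U"), 1L)
    paste0(first, paste0(sample(c("A", "C", "G", "U"), l - 1L, replace = TRUE),
                         collapse = ""))
  }, character(1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
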