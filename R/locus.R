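#' Flag DE miRNAs as inside or outside a named locus
#'
#' A miRNA is "in locus" iff it sits on the locus chromosome and its interval
#' overlaps the locus interval by at least 1 bp (both intervals 0-based
#' half-open; strand is ignored — the locus is treated as a region, not a
#' stranded transcript).
#'
#' @param de_ids character vector of DE miRNA ids.
#' @param annotation data.frame with columns `mirna_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param locus list with `chrom`, `start`, `end` (and optionally `name`).
#' @return List with `flags` (named logical per DE id), `n_de`,
#'   `n_de_in_locus`, `fraction_in_locus`, and `per_chrom` (data.frame of DE
#'   counts per chromosome present in the annotation, zeros included).
#' @export
assign_locus <- function(de_ids, annotation, locus) {
  missing <- setdiff(de_ids, annotation$mirna_id)
  if (length(missing) > 0)
    stop("DE ids absent from the annotation: ", paste(missing, collapse = ", "))
  idx <- match(de_ids, annotation$mirna_id)
  flags <- annotation$chrom[idx] == locus$chrom &
    annotation$start[idx] < locus$end &
    annotation$end[idx] > locus$start
  names(flags) <- de_ids
  chroms <- unique(annotation$chrom)
  per_chrom <- data.frame(
    chrom = chroms,
    n_de = as.integer(table(factor(annotation$chrom[idx], levels = chroms))),
    stringsAsFactors = FALSE)
  list(flags = flags,
       n_de = length(de_ids),
       n_de_in_locus = sum(flags),
       fraction_in_locus = if (length(de_ids) > 0) mean(flags) else NA_real_,
       per_chrom = per_chrom)
}

n_annotated_in_locus <- function(annotation, locus)
  sum(annotation$chrom == locus$chrom &
        annotation$start < locus$end &
        annotation$end > locus$start)

#' Share of the locus miRNA complement that is differentially expressed
#'
#' Returns `100 * n_de_in_locus / n_annotated_in_locus`: the percentage of
#' all miRNAs annotated inside the locus that belong to the supplied DE set
#' (e.g. 32 up-regulated of 101 annotated gives 31.7%).
#'
#' @param de_ids DE miRNA ids (typically the up-regulated set).
#' @inheritParams assign_locus
#' @return Percentage (numeric scalar).
#' @export
locus_fraction_report <- function(de_ids, annotation, locus) {
  k_total <- n_annotated_in_locus(annotation, locus)
  if (k_total == 0)
    stop("no miRNAs are annotated inside the locus; fraction undefined")
  res <- assign_locus(de_ids, annotation, locus)
  100 * res$n_de_in_locus / k_total
}

#' Hypergeometric upper-tail test of locus over-representation
#'
#' With N annotated miRNAs, K inside the locus, n DE miRNAs of which k fall
#' inside the locus, returns P(X >= k) for X ~ Hypergeometric(N, K, n).
#'
#' @inheritParams assign_locus
#' @return Upper-tail p-value.
#' @export
locus_hypergeom_test <- function(de_ids, annotation, locus) {
  N <- nrow(annotation)
  K <- n_annotated_in_locus(annotation, locus)
  n <- length(de_ids)
  k <- assign_locus(de_ids, annotation, locus)$n_de_in_locus
  if (K == 0 || n == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Permutation test of locus over-representation
#'
#' The null resamples the identity of the DE set: `length(de_ids)` miRNA ids
#' are drawn uniformly without replacement from the annotation, `n_perm`
#' times, preserving the genome's clustered annotation structure. The
#' p-value is `(1 + #{permuted fraction >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams assign_locus
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List with `p`, `observed_fraction`, `n_perm`.
#' @export
locus_permutation_test <- function(de_ids, annotation, locus,
                                   n_perm = 999, seed = 1L) {
  obs <- assign_locus(de_ids, annotation, locus)$fraction_in_locus
  n <- length(de_ids)
  if (n == 0) stop("empty DE set")
  in_locus <- annotation$chrom == locus$chrom &
    annotation$start < locus$end & annotation$end > locus$start
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i)
      mean(in_locus[sample.int(nrow(annotation), n)]), numeric(1))
    list(p = (1 + sum(perm >= obs)) / (n_perm + 1),
         observed_fraction = obs, n_perm = n_perm)
  })
}

#' Compare DE effect sizes inside vs outside the locus
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test between locus and
#' non-locus DE miRNAs on the chosen metric.
#'
#' @param de_results data.frame with `mirna_id`, `log2fc`, `padj`.
#' @param in_locus_flags named logical vector over the DE ids (see
#'   [assign_locus()]).
#' @param metric `"abs_log2fc"` or `"neg_log10_padj"`.
#' @return List with `statistic` (U), `p`, `n_in`, `n_out`, `metric`.
#' @export
compare_effect_sizes <- function(de_results, in_locus_flags,
                                 metric = c("abs_log2fc", "neg_log10_padj")) {
  metric <- match.arg(metric)
  idx <- match(names(in_locus_flags), de_results$mirna_id)
  if (anyNA(idx)) stop("in_locus_flags names must match de_results mirna_id")
  vals <- switch(metric,
                 abs_log2fc = abs(de_results$log2fc[idx]),
                 neg_log10_padj = -log10(pmax(de_results$padj[idx], 1e-300)))
  x <- vals[in_locus_flags]
  y <- vals[!in_locus_flags]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 DE miRNAs both inside and outside the locus")
  wt <- wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_in = length(x), n_out = length(y), metric = metric)
}
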