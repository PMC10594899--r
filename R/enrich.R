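#' Hypergeometric pathway enrichment for one miRNA's target genes
#'
#' For each gene set, with universe size N, set size K, n target genes in the
#' universe and k of them in the set, the p-value is the upper hypergeometric
#' tail P(X >= k). P-values are BH-adjusted across the gene sets of this one
#' miRNA. Genes outside the universe are dropped with a warning; gene-set
#' members outside the universe are dropped silently from K.
#'
#' @param target_genes character vector of predicted target gene ids.
#' @param genesets named list of gene-id vectors.
#' @param universe character vector of background gene ids (defaults to the
#'   union of all gene-set members — prefer passing all genes with a UTR).
#' @return data.frame: `pathway`, `k`, `K`, `n`, `N`, `pvalue`, `padj`.
#' @export
hypergeom_enrich <- function(target_genes, genesets, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(unlist(genesets)))
  outside <- setdiff(target_genes, universe)
  if (length(outside) > 0)
    warning(length(outside), " target gene(s) outside the universe dropped")
  targets <- unique(intersect(target_genes, universe))
  n <- length(targets); N <- length(universe)
  K <- vapply(genesets, function(s) sum(!is.na(match(s, universe))), 0L)
  k <- vapply(genesets, function(s)
    sum(!is.na(match(intersect(s, universe), targets))), 0L)
  p <- ifelse(K == 0 | n == 0, 1,
              phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  out <- data.frame(pathway = names(genesets), k = k, K = K, n = n, N = N,
                    pvalue = p, padj = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Top-k pathways of one enrichment result
#'
#' Pathways are sorted by ascending p-value, ties broken by larger number of
#' enriched genes `k`, then lexicographic pathway id, and truncated to
#' `top_k`. Pathways with fewer than `min_k` enriched genes are dropped
#' first (default 1: only pathways actually containing a target gene can
#' enter a top list, mirroring enrichment tools that report only hit
#' pathways).
#'
#' @param results data.frame from [hypergeom_enrich()].
#' @param top_k list length (default 10).
#' @param min_k minimum number of enriched genes (default 1).
#' @return Character vector of pathway ids, best first.
#' @export
rank_top <- function(results, top_k = 10, min_k = 1) {
  res <- results[results$k >= min_k, , drop = FALSE]
  res <- res[order(res$pvalue, -res$k, res$pathway), , drop = FALSE]
  head(res$pathway, top_k)
}

#' Cross-miRNA recurrence of top pathways
#'
#' Counts, for every pathway, the number of per-miRNA top-k lists containing
#' it, and ranks pathways by descending frequency (ties broken by
#' lexicographic id). The fraction divides by the number of miRNA groups
#' analyzed.
#'
#' @param per_mirna_toplists list of character vectors (one per miRNA), as
#'   produced by [rank_top()].
#' @return data.frame: `pathway`, `frequency`, `n_groups`, `fraction`,
#'   `rank`, ordered best first.
#' @export
recurrence <- function(per_mirna_toplists) {
  n_groups <- length(per_mirna_toplists)
  tab <- table(unlist(lapply(per_mirna_toplists, unique)))
  out <- data.frame(pathway = names(tab), frequency = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$pathway), , drop = FALSE]
  out$n_groups <- n_groups
  out$fraction <- if (n_groups > 0) out$frequency / n_groups else NA_real_
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
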