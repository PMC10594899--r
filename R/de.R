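#' Median-of-ratios size factors
#'
#' For every miRNA expressed in all samples, compute the ratio of each
#' sample's count to the miRNA's geometric mean across samples; the sample's
#' size factor is the median of those ratios.
#'
#' @param counts non-negative integer matrix, miRNAs x samples.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable))
    stop("no miRNA has nonzero counts in every sample; ",
         "filter samples or supply deeper data before normalizing")
  sub <- counts[usable, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, median)
  if (any(sf <= 0)) stop("non-positive size factor computed")
  sf
}

#' Per-miRNA two-group negative-binomial Wald test
#'
#' For each miRNA the counts are normalized by the size factors, group means
#' are formed, the NB dispersion alpha (Var = mu + alpha mu^2) is estimated
#' by method of moments pooled across the two groups (floored at 1e-8), and
#' a Wald statistic log2fc / se is referred to a Student t distribution with
#' `n - 2` degrees of freedom. The t reference is a small-sample calibration
#' of the asymptotic normal Wald test: with 5 + 5 samples the plugin variance
#' carries only 8 df of information and a plain normal reference rejects at
#' roughly 8% when the nominal level is 5%, while the t reference holds the
#' type-I error at its nominal level (see the package vignette). The log2
#' fold change is group A over group B, moderated with a +0.5 pseudocount on
#' the normalized group means so zero-mean groups stay finite.
#'
#' @param counts integer matrix, miRNAs x samples.
#' @param factors per-sample size factors (see [size_factors()]).
#' @param groups character vector or factor of length `ncol(counts)` with
#'   exactly two levels; the first level sorted is treated as group A.
#' @return data.frame with `mirna_id`, `base_mean`, `mean_A`, `mean_B`,
#'   `log2fc`, `se_log2fc`, `stat`, `pvalue`, `dispersion`, `all_zero`.
#' @export
nb_test <- function(counts, factors, groups) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (length(factors) != ncol(counts) || length(groups) != ncol(counts))
    stop("factors and groups must match the number of samples")
  a <- groups == lev[1]; b <- !a
  if (sum(a) < 2L || sum(b) < 2L) stop("need >= 2 samples per group")

  y <- sweep(counts, 2, factors, `/`)          # normalized counts
  na <- sum(a); nb <- sum(b)
  m_a <- rowMeans(y[, a, drop = FALSE])
  m_b <- rowMeans(y[, b, drop = FALSE])
  base_mean <- rowMeans(y)

  # Method-of-moments dispersion pooled across groups. Normalized counts are
  # heteroscedastic (Var(y_s) = q/sf_s + alpha q^2), so the Poisson part of
  # the within-group variance is q * mean(1/sf).
  c_a <- mean(1 / factors[a]); c_b <- mean(1 / factors[b])
  v_a <- apply(y[, a, drop = FALSE], 1, var)
  v_b <- apply(y[, b, drop = FALSE], 1, var)
  alpha_a <- (v_a - m_a * c_a) / pmax(m_a, 1e-8)^2
  alpha_b <- (v_b - m_b * c_b) / pmax(m_b, 1e-8)^2
  alpha <- pmax(((na - 1) * alpha_a + (nb - 1) * alpha_b) / (na + nb - 2), 1e-8)

  pc <- 0.5
  log2fc <- log2(m_a + pc) - log2(m_b + pc)
  # Delta-method variance of log(mean) per group under the NB model, with the
  # same pseudocount applied so near-zero means do not explode the statistic.
  var_ma <- (m_a * c_a + alpha * m_a^2) / na
  var_mb <- (m_b * c_b + alpha * m_b^2) / nb
  se <- sqrt(var_ma / (m_a + pc)^2 + var_mb / (m_b + pc)^2) / log(2)

  all_zero <- rowSums(counts) == 0
  stat <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * stats::pt(-abs(stat), df = na + nb - 2)
  stat[all_zero] <- 0
  log2fc[all_zero] <- 0
  pvalue[all_zero] <- 1

  data.frame(mirna_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             base_mean = base_mean, mean_A = m_a, mean_B = m_b,
             log2fc = log2fc, se_log2fc = se, stat = stat, pvalue = pvalue,
             dispersion = alpha, all_zero = all_zero,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Adjusted p-values, each in \[p, 1\].
#' @export
bh_adjust <- function(pvalues) {
  n <- length(pvalues)
  if (n == 0L) return(numeric(0))
  if (any(is.na(pvalues) | pvalues < 0 | pvalues > 1))
    stop("pvalues must lie in [0, 1] with no NA")
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * pvalues[o]))[ro]
}

#' Call differential expression with strict thresholds
#'
#' A miRNA is called up when `padj < alpha` and `log2fc > lfc_min`, down when
#' `padj < alpha` and `log2fc < -lfc_min`; both inequalities are strict.
#'
#' @param results data.frame from [nb_test()]; a `padj` column is added via
#'   [bh_adjust()] when absent.
#' @param alpha adjusted-P threshold (default 0.05).
#' @param lfc_min absolute log2-fold-change threshold (default 1).
#' @return List with the augmented `results` (columns `padj`, `call`) plus
#'   `up` and `down` id vectors.
#' @export
call_de <- function(results, alpha = 0.05, lfc_min = 1) {
  if (is.null(results$padj)) results$padj <- bh_adjust(results$pvalue)
  call <- rep("ns", nrow(results))
  call[results$padj < alpha & results$log2fc > lfc_min] <- "up"
  call[results$padj < alpha & results$log2fc < -lfc_min] <- "down"
  results$call <- call
  list(results = results,
       up = results$mirna_id[call == "up"],
       down = results$mirna_id[call == "down"])
}

log_norm <- function(counts, factors)
  log2(sweep(as.matrix(counts), 2, factors, `/`) + 1)

#' Sample PCA on log-normalized counts
#'
#' PCA of the samples on `log2(count / size_factor + 1)` after centering each
#' miRNA. The sign of each component is fixed by forcing its
#' largest-magnitude loading positive, so results are fully deterministic.
#'
#' @inheritParams nb_test
#' @param n_comp number of components to return (default 2).
#' @return List with `scores` (samples x components) and `var_explained`.
#' @export
pca_samples <- function(counts, factors, n_comp = 2) {
  x <- log_norm(counts, factors)
  xc <- x - rowMeans(x)
  if (all(abs(xc) < 1e-12))
    stop("constant expression matrix: PCA undefined (zero variance)")
  pc <- prcomp(t(xc), center = FALSE, scale. = FALSE)
  n_comp <- min(n_comp, ncol(pc$x))
  for (j in seq_len(n_comp)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x[, seq_len(n_comp), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_comp)])
}

#' Sample-sample Pearson correlation of log-normalized expression
#'
#' @inheritParams nb_test
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(counts, factors)
  cor(log_norm(counts, factors))

#' K-means clustering of miRNA expression patterns
#'
#' Profiles are per-miRNA z-scores of log-normalized expression; miRNAs with
#' zero variance get a flat zero profile. The seed makes k-means labels
#' reproducible.
#'
#' @inheritParams nb_test
#' @param k number of clusters.
#' @param seed RNG seed for the k-means initialization.
#' @return Named integer vector: miRNA id -> cluster id in 1..k.
#' @export
cluster_patterns <- function(counts, factors, k, seed = 1L) {
  x <- log_norm(counts, factors)
  s <- apply(x, 1, sd)
  z <- (x - rowMeans(x)) / ifelse(s > 0, s, 1)
  if (k < 1) stop("k must be >= 1")
  if (k == 1L)
    return(setNames(rep(1L, nrow(z)), rownames(z)))
  with_seed(seed, {
    km <- kmeans(z, centers = k, nstart = 10, iter.max = 50)
    setNames(as.integer(km$cluster), rownames(z))
  })
}
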