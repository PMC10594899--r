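toy_annotation <- function() {
  data.frame(
    mirna_id = sprintf("mir-%02d", 1:10),
    chrom = c(rep("chr1", 5), rep("chr2", 5)),
    start = c(100, 150, 200, 300, 400, 100, 200, 300, 400, 500),
    end = c(122, 172, 222, 322, 422, 122, 222, 322, 422, 522),
    strand = "+", stringsAsFactors = FALSE)
}
toy_locus <- list(name = "L", chrom = "chr1", start = 150, end = 350)

test_that("assign_locus applies the >=1 bp half-open overlap rule", {
  ann <- toy_annotation()
  res <- assign_locus(ann$mirna_id, ann, toy_locus)
  # mir-01 ends at 122 <= 150: out; mir-02..04 overlap; mir-05 starts at 400: out
  expect_equal(unname(res$flags[1:5]), c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_false(any(res$flags[6:10]))            # wrong chromosome
  expect_equal(res$n_de_in_locus, 3)
  expect_equal(sum(res$per_chrom$n_de), res$n_de)

  # feature ending exactly at locus start is out; 1 bp overlap is in
  edge <- data.frame(mirna_id = c("x", "y"), chrom = "chr1",
                     start = c(128, 129), end = c(150, 151), strand = "+")
  fl <- assign_locus(c("x", "y"), edge, toy_locus)$flags
  expect_equal(unname(fl), c(FALSE, TRUE))

  expect_error(assign_locus(c("mir-01", "ghost"), ann, toy_locus), "ghost")
})

test_that("locus fraction report reproduces the in-text arithmetic", {
  # 32 DE of 101 annotated in the locus -> 31.7% (1 d.p.)
  n <- 120
  ann <- data.frame(
    mirna_id = sprintf("m%03d", 1:n), chrom = c(rep("chr18", 101), rep("chr1", 19)),
    start = c(seq(1000, by = 100, length.out = 101), seq(1000, by = 100, length.out = 19)),
    stringsAsFactors = FALSE)
  ann$end <- ann$start + 22
  locus <- list(chrom = "chr18", start = 0, end = 1e6)
  up <- ann$mirna_id[1:32]
  expect_equal(round(locus_fraction_report(up, ann, locus), 1), 31.7)

  empty_locus <- list(chrom = "chr9", start = 0, end = 100)
  expect_error(locus_fraction_report(up, ann, empty_locus), "undefined")
})

test_that("hypergeometric tail equals exhaustive enumeration", {
  # spec instance N=20, K=5, n=4, k=3 plus random small instances
  cases <- rbind(c(20, 5, 4, 3), c(10, 4, 5, 2), c(25, 10, 6, 6),
                 c(12, 12, 3, 3), c(15, 0, 4, 0))
  for (i in seq_len(nrow(cases))) {
    N <- cases[i, 1]; K <- cases[i, 2]; n <- cases[i, 3]; k <- cases[i, 4]
    ann <- data.frame(mirna_id = sprintf("m%02d", 1:N),
                      chrom = c(rep("chrL", K), rep("chrO", N - K)),
                      start = seq(100, by = 100, length.out = N),
                      stringsAsFactors = FALSE)
    ann$end <- ann$start + 22
    locus <- list(chrom = "chrL", start = 0, end = 1e6)
    de_ids <- c(ann$mirna_id[seq_len(k)],
                ann$mirna_id[K + seq_len(n - k)])   # exactly k inside
    expect_equal(locus_hypergeom_test(de_ids, ann, locus),
                 oracle_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
  # K = N: every draw is fully inside, p = 1
  annK <- data.frame(mirna_id = c("a", "b", "c"), chrom = "chrL",
                     start = c(10, 50, 90), end = c(32, 72, 112),
                     stringsAsFactors = FALSE)
  expect_equal(locus_hypergeom_test(c("a", "b"), annK,
                                    list(chrom = "chrL", start = 0, end = 200)), 1)
})

test_that("permutation test: bounds, degeneracy, row-order invariance", {
  cfg <- small_sim(seed = 2L)
  sim <- simulate_annotation(cfg)
  tr <- simulate_counts(sim$annotation, cfg, sim$locus)$truth

  # planted all-in-locus set at n_perm = 999 attains the minimum p
  res <- locus_permutation_test(tr$up_ids, sim$annotation, sim$locus,
                                n_perm = 999, seed = 8L)
  expect_equal(res$p, 1 / 1000)
  expect_equal(res$observed_fraction, 1)

  # all annotated miRNAs inside the locus -> p = 1
  annL <- data.frame(mirna_id = c("a", "b", "c", "d"), chrom = "chrL",
                     start = c(0, 100, 200, 300), end = c(22, 122, 222, 322),
                     stringsAsFactors = FALSE)
  expect_equal(locus_permutation_test(c("a", "b"), annL,
                                      list(chrom = "chrL", start = 0, end = 400),
                                      n_perm = 99, seed = 1)$p, 1)

  # invariance to annotation row order
  shuf <- sim$annotation[sample(nrow(sim$annotation)), ]
  res2 <- locus_permutation_test(tr$up_ids, shuf, sim$locus,
                                 n_perm = 999, seed = 8L)
  expect_equal(res2$p, res$p)

  expect_error(locus_permutation_test(character(0), sim$annotation, sim$locus),
               "empty")
})

test_that("effect-size comparison detects a planted locus shift", {
  set.seed(31)
  de <- data.frame(mirna_id = sprintf("m%02d", 1:60),
                   log2fc = c(rnorm(30, 3), rnorm(30, 1)),
                   padj = runif(60, 0, 0.05), stringsAsFactors = FALSE)
  flags <- setNames(rep(c(TRUE, FALSE), each = 30), de$mirna_id)
  res <- compare_effect_sizes(de, flags, metric = "abs_log2fc")
  expect_lt(res$p, 0.001)
  expect_equal(res$n_in, 30)

  flags1 <- setNames(c(TRUE, rep(FALSE, 59)), de$mirna_id)
  expect_error(compare_effect_sizes(de, flags1), ">= 2")
})
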