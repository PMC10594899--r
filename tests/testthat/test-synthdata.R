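test_that("every generator is byte-identical under the same seed", {
  cfg <- small_sim(seed = 42L)
  ann1 <- simulate_annotation(cfg); ann2 <- simulate_annotation(cfg)
  expect_identical(ann1, ann2)
  cts1 <- simulate_counts(ann1$annotation, cfg, ann1$locus)
  cts2 <- simulate_counts(ann1$annotation, cfg, ann1$locus)
  expect_identical(cts1, cts2)
  sq1 <- simulate_sequences(ann1$annotation, cfg, cts1$truth)
  sq2 <- simulate_sequences(ann1$annotation, cfg, cts1$truth)
  expect_identical(sq1, sq2)
  expect_identical(simulate_genesets(cfg, sq1$target_truth),
                   simulate_genesets(cfg, sq1$target_truth))
  expect_identical(simulate_reads(ann1$annotation, cfg, sq1$mirna_seqs),
                   simulate_reads(ann1$annotation, cfg, sq1$mirna_seqs))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  # a different seed changes the output
  expect_false(identical(ann1, simulate_annotation(small_sim(seed = 43L))))
})

test_that("annotation places the cluster inside the locus interval", {
  cfg <- sim_config(n_locus_mirnas = 101, n_up_planted = 32, seed = 7L)
  sim <- simulate_annotation(cfg)
  ann <- sim$annotation
  in_locus <- ann[ann$chrom == cfg$locus_chrom &
                    ann$start < cfg$locus_interval[2] &
                    ann$end > cfg$locus_interval[1], ]
  expect_equal(nrow(in_locus), 101)
  expect_true(all(in_locus$start >= cfg$locus_interval[1]))
  expect_true(all(in_locus$end <= cfg$locus_interval[2]))
  o <- order(in_locus$start)                       # non-overlapping features
  expect_true(all(in_locus$start[o][-1] >= in_locus$end[o][-101]))
  expect_false(any(ann$chrom[!ann$mirna_id %in% in_locus$mirna_id] ==
                     cfg$locus_chrom))

  # empty locus
  cfg0 <- small_sim()
  cfg0$n_locus_mirnas <- 0L; cfg0$n_up_planted <- 0L
  ann0 <- simulate_annotation(cfg0)$annotation
  expect_equal(sum(ann0$chrom == cfg0$locus_chrom), 0)

  # interval too small for non-overlapping placement
  cfg_bad <- small_sim()
  cfg_bad$locus_interval <- c(1000, 1200)  # 200 bp for 30 features
  expect_error(simulate_annotation(cfg_bad), "too small")
})

test_that("counts follow the NB model and the planted truth structure", {
  # moment check: fixed mu = 1000, alpha = 0.1, many miRNAs, known factors
  cfg <- sim_config(n_mirnas_total = 10000, n_locus_mirnas = 101,
                    n_up_planted = 0, n_down_planted = 0, lfc_up = 0,
                    lfc_down = 0, nb_mean_log_range = c(3, 3),
                    nb_dispersion = 0.1, seed = 5L)
  ann <- simulate_annotation(cfg)
  cts <- simulate_counts(ann$annotation, cfg, ann$locus)
  for (s in c(1, 6)) {                    # one sample per group suffices
    mu_s <- 1000 * cts$size_factors_true[s]
    v_s <- mu_s + 0.1 * mu_s^2
    se_mean <- sqrt(v_s / 10000)
    expect_lt(abs(mean(cts$counts[, s]) - mu_s), 4 * se_mean)
    expect_lt(abs(var(cts$counts[, s]) / v_s - 1), 0.1)
  }

  # structural truth: up inside the locus, down outside
  cfg2 <- small_sim(seed = 3L)
  ann2 <- simulate_annotation(cfg2)
  cts2 <- simulate_counts(ann2$annotation, cfg2, ann2$locus)
  tr <- cts2$truth
  expect_length(tr$up_ids, cfg2$n_up_planted)
  expect_length(tr$down_ids, cfg2$n_down_planted)
  fl_up <- assign_locus(tr$up_ids, ann2$annotation, ann2$locus)$flags
  fl_dn <- assign_locus(tr$down_ids, ann2$annotation, ann2$locus)$flags
  expect_true(all(fl_up))
  expect_false(any(fl_dn))

  # zero effect size => no planted truth
  cfg0 <- small_sim()
  cfg0$lfc_up <- 0; cfg0$lfc_down <- 0
  ann0 <- simulate_annotation(cfg0)
  tr0 <- simulate_counts(ann0$annotation, cfg0, ann0$locus)$truth
  expect_true(all(tr0$de_truth == "null"))

  cfg_bad <- small_sim()
  cfg_bad$nb_dispersion <- -1
  expect_error(simulate_counts(ann2$annotation, cfg_bad), "dispersion")
})

test_that("sequences have miRNA lengths 21-22, U bias, and planted sites", {
  cfg <- sim_config(n_mirnas_total = 1000, n_locus_mirnas = 101,
                    n_up_planted = 0, n_down_planted = 0, u_bias = 0.6,
                    seed = 9L)
  ann <- simulate_annotation(cfg)
  seqs <- simulate_sequences(ann$annotation, cfg)
  lens <- nchar(seqs$mirna_seqs)
  expect_true(all(lens %in% c(21L, 22L)))
  u_frac <- mean(substr(seqs$mirna_seqs, 1, 1) == "U")
  se <- sqrt(0.6 * 0.4 / 1000)
  expect_lt(abs(u_frac - 0.6), 3 * se)
  expect_true(all(nchar(seqs$utr_seqs) == cfg$utr_length))

  # full coverage: every up-truth miRNA has a planted site, and the UTR
  # really contains the reverse complement of the full mature sequence
  cfg2 <- small_sim(seed = 21L)
  ann2 <- simulate_annotation(cfg2)
  tr2 <- simulate_counts(ann2$annotation, cfg2, ann2$locus)$truth
  sq2 <- simulate_sequences(ann2$annotation, cfg2, tr2)
  tt <- sq2$target_truth
  expect_setequal(unique(tt$mirna_id), tr2$up_ids)
  for (r in seq_len(nrow(tt))) {
    m <- sq2$mirna_seqs[[tt$mirna_id[r]]]
    u <- sq2$utr_seqs[[tt$gene_id[r]]]
    planted <- substr(u, tt$site_start[r] + 1, tt$site_start[r] + nchar(m))
    expect_identical(planted, as.character(Biostrings::reverseComplement(
      Biostrings::RNAString(m))))
  }
})

test_that("gene sets contain the planted pathway with full truth coverage", {
  cfg <- small_sim(seed = 13L)
  ann <- simulate_annotation(cfg)
  tr <- simulate_counts(ann$annotation, cfg, ann$locus)$truth
  sq <- simulate_sequences(ann$annotation, cfg, tr)
  gs <- simulate_genesets(cfg, sq$target_truth)
  expect_true(gs$pathway_truth %in% names(gs$genesets))
  expect_true(all(unique(sq$target_truth$gene_id) %in%
                    gs$genesets[[gs$pathway_truth]]))
  expect_true(all(unlist(gs$genesets) %in% gs$universe))

  cfg1 <- small_sim(); cfg1$n_pathways <- 1L
  gs1 <- simulate_genesets(cfg1, sq$target_truth)
  expect_length(gs1$genesets, 1L)

  cfg_bad <- small_sim(); cfg_bad$geneset_size_range <- c(5, 1000)
  expect_error(simulate_genesets(cfg_bad, sq$target_truth), "universe")
})

test_that("read sets conserve total abundance and exercise the length filter", {
  cfg <- small_sim(seed = 17L)
  ann <- simulate_annotation(cfg)
  rs <- simulate_reads(ann$annotation, cfg)
  expect_equal(sum(rs$reads$abundance), cfg$n_reads)
  lens <- nchar(rs$reads$sequence)
  expect_true(16L %in% lens && 40L %in% lens)
  expect_identical(names(rs$refsets),
                   c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA"))

  # no decoys, no junk: everything annotates as miRNA
  cfg0 <- small_sim(seed = 17L)
  cfg0$decoy_fraction <- 0; cfg0$other_fraction <- 0
  rs0 <- simulate_reads(ann$annotation, cfg0)
  ab0 <- annotate_by_priority(rs0$reads, rs0$refsets)
  expect_true(all(ab0$category == "miRNA"))
})

test_that("qPCR tables encode the configured fold change in Ct space", {
  cfg <- small_sim()
  cfg$qpcr_fold_change <- 16; cfg$qpcr_noise_sd <- 0
  tab <- simulate_qpcr(cfg)
  a <- tab[tab$group == "A" & tab$assay != "U6", "ct"]
  b <- tab[tab$group == "B" & tab$assay != "U6", "ct"]
  expect_equal(unique(a) - unique(b), -4)  # 16-fold = 4 cycles earlier

  cfg$qpcr_fold_change <- 1
  tab1 <- simulate_qpcr(cfg)   # no effect, no noise: one Ct for all samples
  expect_length(unique(tab1$ct[tab1$assay != "U6"]), 1L)
})
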