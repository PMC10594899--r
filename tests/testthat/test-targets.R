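rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::RNAString(x)))

test_that("seed classes are assigned per the canonical definitions", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"            # 22 nt, seed (2-8) GAGGUAG
  core7 <- rc(substr(m, 2, 8))             # appears 5'->3' in the UTR
  pad <- function(...) paste0(...)

  u8 <- pad("CCCCC", core7, "A", "CCCCC")  # rc(2-8) followed by A -> 8mer
  s8 <- find_seed_sites(m, u8)
  expect_equal(s8$class, "8mer")
  expect_equal(s8$start, 5); expect_equal(s8$end, 13)

  u7 <- pad("CCCCC", core7, "G", "CCCCC")  # no A -> 7mer-m8
  expect_equal(find_seed_sites(m, u7)$class, "7mer-m8")

  core6 <- rc(substr(m, 2, 7))
  u7a <- pad("GGGGG", core6, "A", "GGGGG") # rc(2-7) + A, no m8 pair -> 7mer-A1
  expect_equal(find_seed_sites(m, u7a)$class, "7mer-A1")
  u6 <- pad("GGGGG", core6, "G", "GGGGG")
  expect_equal(find_seed_sites(m, u6)$class, "6mer")

  # U/T equivalence on input
  expect_identical(find_seed_sites(chartr("U", "T", m), chartr("U", "T", u8)),
                   s8)

  # a UTR with no complement of the core gives no hits
  expect_equal(nrow(find_seed_sites(m, strrep("C", 60))), 0)
})

test_that("seed scan equals the brute-force oracle on random pairs", {
  set.seed(71)
  n_checked <- 0
  for (i in 1:300) {
    m <- rand_rna(sample(21:22, 1))
    u <- rand_rna(sample(c(60, 120), 1))
    if (i %% 3 == 0) {     # implant a seed core so hits are well represented
      core <- rc(substr(m, 2, 7))
      pos <- sample(nchar(u) - 6, 1)
      substr(u, pos, pos + 5) <- core
    }
    got <- find_seed_sites(m, u)
    want <- oracle_seed_scan(m, u)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
    n_checked <- n_checked + nrow(want)
  }
  expect_gt(n_checked, 50)  # the loop must have exercised real hits
})

test_that("duplex alignment scores follow the declared constants", {
  expect_equal(align_duplex("UGAGGUAGUAGGUUGUAUAGUU", "")$score, 0)

  # perfect complement of a 22-mer: 15 non-seed * 5 + 7 seed * 5 * 4 = 215
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  expect_equal(align_duplex(m, rc(m))$score, 215)
  # and of a 21-mer: 14 * 5 + 7 * 20 = 210
  m21 <- substr(m, 1, 21)
  expect_equal(align_duplex(m21, rc(m21))$score, 210)

  # a G:U wobble scores 2, scaled by 4 inside the seed
  m2 <- strrep("G", 22)
  w_seed_wobble <- strrep("C", 22)
  substr(w_seed_wobble, 18, 18) <- "U"    # pairs miRNA position 5 (seed)
  expect_equal(align_duplex(m2, w_seed_wobble)$score, 215 - 20 + 8)
  w_out_wobble <- strrep("C", 22)
  substr(w_out_wobble, 2, 2) <- "U"       # pairs miRNA position 21 (3' region)
  expect_equal(align_duplex(m2, w_out_wobble)$score, 215 - 5 + 2)
})

test_that("alignment equals an independent local aligner on random pairs", {
  set.seed(72)
  for (i in 1:200) {
    m <- rand_rna(sample(19:22, 1))
    w <- rand_rna(sample(25:40, 1))
    expect_equal(align_duplex(m, w)$score, oracle_align_score(m, w),
                 info = paste(m, w))
  }
})

test_that("duplex energy sums stack terms", {
  expect_equal(duplex_energy(data.frame(mirna_pos = integer(0),
                                        window_pos = integer(0),
                                        type = character(0))), 0)
  # 10 consecutive G:C pairs -> 9 stacks at -3
  gc10 <- data.frame(mirna_pos = 10:1, window_pos = 1:10, type = "GC")
  expect_equal(duplex_energy(gc10), -27)
  # mixed stacks: GC|AU -> -2, AU|GU -> -1
  mix <- data.frame(mirna_pos = 3:1, window_pos = 1:3,
                    type = c("GC", "AU", "GU"))
  expect_equal(duplex_energy(mix), -3)
  # adding pairs to a contiguous duplex never raises the energy
  e_prev <- 0
  for (len in 2:12) {
    d <- data.frame(mirna_pos = len:1, window_pos = 1:len,
                    type = rep(c("AU", "GC"), length.out = len))
    e <- duplex_energy(d)
    expect_lte(e, e_prev)
    e_prev <- e
  }
  # a mismatch interrupts stacking
  broken <- data.frame(mirna_pos = 5:1, window_pos = 1:5,
                       type = c("GC", "GC", "MM", "GC", "GC"))
  expect_equal(duplex_energy(broken), -6)
})

test_that("predict_targets applies both strict filters and flags best sites", {
  m <- setNames("UGAGGUAGUAGGUUGUAUAGUU", "mir-a")
  u_hit <- paste0(strrep("C", 30), rc(m[[1]]), strrep("C", 30))
  u_seed_only <- paste0(strrep("C", 30), rc(substr(m[[1]], 2, 8)), "A",
                        strrep("C", 30))
  utrs <- c(hit = u_hit, weak = u_seed_only, none = strrep("C", 80))
  hits <- predict_targets(m, utrs)
  # only the perfect-complement site passes score > 150 & energy < -20
  expect_equal(unique(hits$gene_id), "hit")
  expect_true(all(hits$score > 150 & hits$energy < -20))
  expect_equal(sum(hits$best[hits$gene_id == "hit"]), 1)

  # planted site is recovered with the maximal score among windows
  expect_equal(max(hits$score), align_duplex(m[[1]], rc(m[[1]]))$score)

  # filters are strict: a site at exactly the threshold is dropped
  expect_equal(nrow(predict_targets(m, utrs["hit"], score_min = 215)), 0)
  expect_equal(nrow(predict_targets(m, utrs["hit"], energy_max = -100)), 0)

  # randomizing the UTR destroys the planted site
  set.seed(5)
  u_rand <- rand_rna(80)
  expect_true(nrow(predict_targets(m, c(r = u_rand))) == 0 ||
                all(predict_targets(m, c(r = u_rand))$gene_id == "r"))
})

test_that("prediction intersection works on (miRNA, gene) keys", {
  a <- data.frame(mirna_id = c("m1", "m1", "m2"), gene_id = c("g1", "g2", "g1"),
                  score = 1:3, stringsAsFactors = FALSE)
  b <- data.frame(mirna_id = c("m1", "m3"), gene_id = c("g2", "g1"),
                  stringsAsFactors = FALSE)
  got <- intersect_predictions(a, b)
  expect_equal(nrow(got), 1)
  expect_equal(got$gene_id, "g2")
  expect_equal(nrow(intersect_predictions(a, a)), 3)         # identity
  expect_equal(nrow(intersect_predictions(a, b[0, ])), 0)    # disjoint
  # brute-force key check on random tables
  set.seed(9)
  ra <- data.frame(mirna_id = sample(paste0("m", 1:5), 40, TRUE),
                   gene_id = sample(paste0("g", 1:8), 40, TRUE),
                   stringsAsFactors = FALSE)
  rb <- data.frame(mirna_id = sample(paste0("m", 1:5), 40, TRUE),
                   gene_id = sample(paste0("g", 1:8), 40, TRUE),
                   stringsAsFactors = FALSE)
  manual <- mapply(function(mi, gi) any(rb$mirna_id == mi & rb$gene_id == gi),
                   ra$mirna_id, ra$gene_id)
  expect_equal(nrow(intersect_predictions(ra, rb)), sum(manual))
})
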