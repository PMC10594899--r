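#' Simulation configuration for the synthetic small-RNA study
#'
#' Builds and validates the configuration object consumed by all
#' `simulate_*()` generators. Defaults mirror the scale of a two-group
#' (5 vs 5) sheep skin small-RNA study: ~150 known miRNAs of which 101 sit
#' in one dense cluster (an imprinted Dlk1-Gtl2-like locus) on a single
#' chromosome, 32 planted up-regulated miRNAs all inside that cluster, and
#' 48 planted down-regulated miRNAs scattered over the other chromosomes.
#'
#' @param n_chroms number of chromosomes (default 26, the sheep autosomes).
#' @param chrom_length length in bp of every simulated chromosome.
#' @param n_mirnas_total total number of annotated miRNAs.
#' @param locus_chrom chromosome carrying the dense cluster.
#' @param locus_interval numeric length-2, 0-based half-open interval of the
#'   cluster on `locus_chrom`.
#' @param n_locus_mirnas number of miRNAs placed inside `locus_interval`.
#' @param n_up_planted number of up-regulated miRNAs, all inside the locus.
#' @param n_down_planted number of down-regulated miRNAs, all outside it.
#' @param lfc_up,lfc_down planted log2 fold changes (group A over group B).
#' @param nb_mean_log_range log10 bounds for baseline expression means.
#' @param nb_dispersion NB dispersion alpha with Var = mu + alpha * mu^2.
#' @param n_per_group samples per group.
#' @param n_genes number of genes with a 3'UTR in the simulated FASTA.
#' @param utr_length 3'UTR length in nt.
#' @param n_pathways number of gene sets in the simulated GMT.
#' @param geneset_size_range inclusive bounds for gene-set sizes.
#' @param planted_pathway_coverage fraction of up-planted miRNAs given a
#'   planted target gene inside the planted pathway.
#' @param u_bias probability that a mature miRNA starts with U.
#' @param n_reads total read abundance for [simulate_reads()].
#' @param decoy_fraction fraction of read mass from rRNA/tRNA/snRNA/snoRNA
#'   reference fragments.
#' @param other_fraction fraction of read mass from unclassifiable sequences.
#' @param qpcr_fold_change true fold change (group A over B) for
#'   [simulate_qpcr()].
#' @param qpcr_noise_sd Gaussian Ct noise standard deviation, cycles.
#' @param qpcr_n_per_group biological replicates per group in the qPCR table.
#' @param seed root RNG seed; per-operation streams are derived from it via
#'   [derive_seed()].
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$n_up_planted
sim_config <- function(n_chroms = 26,
                       chrom_length = 3e6,
                       n_mirnas_total = 150,
                       locus_chrom = "chr18",
                       locus_interval = c(1e6, 1.4e6),
                       n_locus_mirnas = 101,
                       n_up_planted = 32,
                       n_down_planted = 48,
                       lfc_up = 2,
                       lfc_down = -2,
                       nb_mean_log_range = c(1, 3),
                       nb_dispersion = 0.05,
                       n_per_group = 5,
                       n_genes = 200,
                       utr_length = 300,
                       n_pathways = 20,
                       geneset_size_range = c(10, 40),
                       planted_pathway_coverage = 1,
                       u_bias = 0.6,
                       n_reads = 50000,
                       decoy_fraction = 0.15,
                       other_fraction = 0.05,
                       qpcr_fold_change = 8,
                       qpcr_noise_sd = 0.25,
                       qpcr_n_per_group = 3,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  if (!cfg$locus_chrom %in% chroms)
    stop("locus_chrom '", cfg$locus_chrom, "' is not among the ", cfg$n_chroms,
         " simulated chromosomes")
  if (cfg$n_up_planted > cfg$n_locus_mirnas)
    stop("n_up_planted must not exceed n_locus_mirnas")
  if (cfg$n_locus_mirnas > cfg$n_mirnas_total)
    stop("n_locus_mirnas must not exceed n_mirnas_total")
  if (cfg$n_down_planted > cfg$n_mirnas_total - cfg$n_locus_mirnas)
    stop("n_down_planted exceeds the number of miRNAs outside the locus")
  li <- cfg$locus_interval
  if (length(li) != 2L || li[1] < 0 || li[2] <= li[1] || li[2] > cfg$chrom_length)
    stop("locus_interval must be a 0-based half-open interval within its chromosome")
  if (cfg$planted_pathway_coverage <= 0 || cfg$planted_pathway_coverage > 1)
    stop("planted_pathway_coverage must be in (0, 1]")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  counts <- c(cfg$n_chroms, cfg$n_mirnas_total, cfg$n_per_group, cfg$n_genes,
              cfg$n_pathways, cfg$utr_length, cfg$qpcr_n_per_group)
  if (any(counts < 1)) stop("all size parameters must be positive")
  invisible(cfg)
}

MATURE_WIDTH <- 22L  # annotated feature width, bp

#' Simulate a miRNA genome annotation with one dense cluster
#'
#' Places `n_locus_mirnas` non-overlapping features inside the configured
#' locus interval and scatters the remaining miRNAs uniformly over the other
#' chromosomes, emulating a genome in which one imprinted domain carries a
#' large clustered miRNA block.
#'
#' @param config a [sim_config()] object.
#' @return A list with `annotation` (data.frame: `mirna_id`, `chrom`,
#'   `start`, `end` 0-based half-open, `strand`) and `locus` (list with
#'   `name`, `chrom`, `start`, `end`).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "simulate_annotation"), {
    n <- config$n_mirnas_total
    ids <- sprintf("mir-%03d", seq_len(n))
    in_locus_ids <- if (config$n_locus_mirnas > 0)
      sort(sample(ids, config$n_locus_mirnas)) else character(0)
    out_ids <- setdiff(ids, in_locus_ids)

    li <- config$locus_interval
    k <- config$n_locus_mirnas
    locus_df <- NULL
    if (k > 0) {
      slot <- floor((li[2] - li[1]) / k)
      if (slot < MATURE_WIDTH)
        stop("locus_interval too small to hold ", k,
             " non-overlapping features of width ", MATURE_WIDTH)
      starts <- li[1] + (seq_len(k) - 1L) * slot +
        sample.int(slot - MATURE_WIDTH + 1L, k, replace = TRUE) - 1L
      locus_df <- data.frame(
        mirna_id = in_locus_ids, chrom = config$locus_chrom,
        start = starts, end = starts + MATURE_WIDTH,
        strand = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE)
    }

    other_chroms <- setdiff(paste0("chr", seq_len(config$n_chroms)),
                            config$locus_chrom)
    m <- length(out_ids)
    out_df <- NULL
    if (m > 0) {
      starts <- sample.int(config$chrom_length - MATURE_WIDTH, m, replace = TRUE)
      out_df <- data.frame(
        mirna_id = out_ids,
        chrom = sample(other_chroms, m, replace = TRUE),
        start = starts, end = starts + MATURE_WIDTH,
        strand = sample(c("+", "-"), m, replace = TRUE),
        stringsAsFactors = FALSE)
    }

    ann <- rbind(locus_df, out_df)
    ann <- ann[order(ann$mirna_id), , drop = FALSE]
    rownames(ann) <- NULL
    list(annotation = ann,
         locus = list(name = "locus", chrom = config$locus_chrom,
                      start = li[1], end = li[2]))
  })
}

#' Simulate a two-group NB count matrix with planted DE miRNAs
#'
#' Counts follow NB(mu, alpha) with Var = mu + alpha mu^2. Per-sample size
#' factors are drawn log-uniform in \[0.5, 2\] to exercise normalization.
#' Up-regulated miRNAs (group A mean multiplied by `2^lfc_up`) are sampled
#' from the annotation rows inside the locus; down-regulated miRNAs from the
#' rows outside it.
#'
#' @param annotation,locus output of [simulate_annotation()].
#' @param config a [sim_config()] object.
#' @return List with `counts` (integer matrix, miRNA x sample), `groups`
#'   (named character vector, `"A"` = newborn-like, `"B"` = adult-like),
#'   `size_factors_true`, and `truth` (list: `de_truth` named character
#'   vector over {up, down, null}; later stages add to it).
#' @export
simulate_counts <- function(annotation, config, locus = NULL) {
  validate_sim_config(config)
  if (anyDuplicated(annotation$mirna_id) > 0)
    stop("annotation miRNA ids must be unique")
  if (is.null(locus))
    locus <- list(chrom = config$locus_chrom,
                  start = config$locus_interval[1],
                  end = config$locus_interval[2])
  with_seed(derive_seed(config$seed, "simulate_counts"), {
    ids <- annotation$mirna_id
    n <- length(ids)
    in_locus <- annotation$chrom == locus$chrom &
      annotation$start < locus$end & annotation$end > locus$start

    de_truth <- setNames(rep("null", n), ids)
    up_ids <- down_ids <- character(0)
    if (config$lfc_up != 0 && config$n_up_planted > 0) {
      up_ids <- sample(ids[in_locus], config$n_up_planted)
      de_truth[up_ids] <- "up"
    }
    if (config$lfc_down != 0 && config$n_down_planted > 0) {
      down_ids <- sample(ids[!in_locus], config$n_down_planted)
      de_truth[down_ids] <- "down"
    }

    mu0 <- 10^runif(n, config$nb_mean_log_range[1], config$nb_mean_log_range[2])
    lfc <- ifelse(de_truth == "up", config$lfc_up,
                  ifelse(de_truth == "down", config$lfc_down, 0))
    npg <- config$n_per_group
    sf <- 2^runif(2 * npg, log2(0.5), log2(2))
    samples <- c(paste0("A", seq_len(npg)), paste0("B", seq_len(npg)))
    groups <- setNames(rep(c("A", "B"), each = npg), samples)

    mu_a <- mu0 * 2^lfc        # group A carries the planted effect
    mu_mat <- cbind(matrix(mu_a, n, npg), matrix(mu0, n, npg))
    mu_mat <- sweep(mu_mat, 2, sf, `*`)
    counts <- matrix(rnbinom(n * 2 * npg, mu = mu_mat,
                             size = 1 / config$nb_dispersion),
                     n, 2 * npg, dimnames = list(ids, samples))
    storage.mode(counts) <- "integer"
    list(counts = counts, groups = groups, size_factors_true = sf,
         truth = list(de_truth = de_truth, up_ids = sort(up_ids),
                      down_ids = sort(down_ids)))
  })
}

# A mature sequence used for target planting must carry at least one G or C
# after position 1: this guarantees its perfect-complement duplex has one
# stack stronger than -1, so a 21-mer site's energy is strictly below -20.
ensure_gc <- function(seq) {
  body <- substring(seq, 2L)
  if (grepl("[GC]", body)) return(seq)
  pos <- sample(nchar(body), 1L)
  substr(body, pos, pos) <- sample(c("G", "C"), 1L)
  paste0(substring(seq, 1L, 1L), body)
}

#' Simulate mature miRNA and 3'UTR sequences with planted target sites
#'
#' Mature miRNAs are random 21-22 nt RNA strings whose first base is U with
#' probability `u_bias`. For a `planted_pathway_coverage` fraction of the
#' up-regulated truth miRNAs, one UTR receives the exact reverse complement
#' of the full mature sequence, guaranteeing a maximal-score target site.
#'
#' @param annotation annotation data.frame from [simulate_annotation()].
#' @param config a [sim_config()] object.
#' @param truth optional truth list from [simulate_counts()]; when supplied,
#'   target sites are planted for its `up_ids`.
#' @return List with `mirna_seqs` and `utr_seqs` (named character vectors,
#'   RNA alphabet) and `target_truth` (data.frame: `mirna_id`, `gene_id`,
#'   `site_start` 0-based).
#' @export
simulate_sequences <- function(annotation, config, truth = NULL) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "simulate_sequences"), {
    ids <- annotation$mirna_id
    mirna_seqs <- setNames(
      vapply(random_rna(length(ids), c(21L, 22L), first_u_prob = config$u_bias),
             ensure_gc, character(1L), USE.NAMES = FALSE),
      ids)

    gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
    utr_seqs <- setNames(random_rna(config$n_genes, config$utr_length), gene_ids)

    target_truth <- data.frame(mirna_id = character(0), gene_id = character(0),
                               site_start = integer(0), stringsAsFactors = FALSE)
    up_ids <- truth$up_ids %||% character(0)
    if (length(up_ids) > 0) {
      n_cov <- ceiling(config$planted_pathway_coverage * length(up_ids))
      covered <- sort(sample(up_ids, n_cov))
      host_genes <- sample(gene_ids, n_cov,
                           replace = n_cov > length(gene_ids))
      for (i in seq_len(n_cov)) {
        site <- rc_rna(mirna_seqs[[covered[i]]])
        w <- nchar(site)
        g <- host_genes[i]
        pos <- sample.int(config$utr_length - w + 1L, 1L)  # 1-based
        u <- utr_seqs[[g]]
        substr(u, pos, pos + w - 1L) <- site
        utr_seqs[[g]] <- u
        target_truth <- rbind(target_truth, data.frame(
          mirna_id = covered[i], gene_id = g, site_start = pos - 1L,
          stringsAsFactors = FALSE))
      }
    }
    list(mirna_seqs = mirna_seqs, utr_seqs = utr_seqs,
         target_truth = target_truth)
  })
}

#' Simulate GMT-style gene sets with one planted recurrent pathway
#'
#' One pathway is seeded with every gene appearing in `target_truth` (the
#' planted targets of the up-regulated miRNAs) and padded with random genes;
#' the remaining pathways are uniform random draws from the gene universe.
#'
#' @param config a [sim_config()] object.
#' @param target_truth data.frame from [simulate_sequences()].
#' @return List with `genesets` (named list of gene-id vectors), `universe`
#'   (all gene ids) and `pathway_truth` (the planted pathway id).
#' @export
simulate_genesets <- function(config, target_truth) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "simulate_genesets"), {
    universe <- sprintf("gene%04d", seq_len(config$n_genes))
    rng <- config$geneset_size_range
    if (rng[2] > config$n_genes)
      stop("geneset_size_range exceeds the gene universe size")
    pw_ids <- sprintf("PW%03d", seq_len(config$n_pathways))
    planted <- sample(pw_ids, 1L)

    truth_genes <- unique(target_truth$gene_id)
    if (length(truth_genes) > config$n_genes)
      stop("target_truth references genes outside the universe")
    sizes <- sample(seq(rng[1], rng[2]), config$n_pathways, replace = TRUE)
    genesets <- lapply(seq_along(pw_ids), function(i) {
      if (pw_ids[i] == planted) {
        size <- max(sizes[i], length(truth_genes))
        pad <- sample(setdiff(universe, truth_genes),
                      size - length(truth_genes))
        sort(c(truth_genes, pad))
      } else sort(sample(universe, sizes[i]))
    })
    names(genesets) <- pw_ids
    list(genesets = genesets, universe = universe, pathway_truth = planted)
  })
}

#' Simulate a deduplicated small-RNA read set plus reference sets
#'
#' Unique reads (sequence, abundance) are drawn from the mature miRNAs plus
#' fragments of decoy rRNA/tRNA/snRNA/snoRNA references and random "other"
#' sequences. Lengths span 16-40 nt so the 18-36 nt filter is exercised;
#' reads of length 16 and 40 are always present when `other_fraction > 0`.
#'
#' @param annotation annotation data.frame (supplies miRNA ids).
#' @param config a [sim_config()] object.
#' @param mirna_seqs optional named mature sequences; simulated when absent.
#' @return List with `reads` (data.frame: `sequence`, `abundance`) and
#'   `refsets` (ordered named list of reference sequence vectors:
#'   miRNA, rRNA, tRNA, snRNA, snoRNA).
#' @export
simulate_reads <- function(annotation, config, mirna_seqs = NULL) {
  validate_sim_config(config)
  if (is.null(mirna_seqs))
    mirna_seqs <- simulate_sequences(annotation, config)$mirna_seqs
  with_seed(derive_seed(config$seed, "simulate_reads"), {
    ref_lens <- c(rRNA = 120L, tRNA = 75L, snRNA = 100L, snoRNA = 80L)
    decoys <- lapply(names(ref_lens), function(cat)
      setNames(random_rna(4L, ref_lens[[cat]]), paste0(cat, "_", 1:4)))
    names(decoys) <- names(ref_lens)
    refsets <- c(list(miRNA = mirna_seqs), decoys)

    total <- config$n_reads
    n_decoy <- round(config$decoy_fraction * total)
    n_other <- round(config$other_fraction * total)
    n_mirna <- total - n_decoy - n_other

    w <- runif(length(mirna_seqs))
    mirna_draw <- sample(unname(mirna_seqs), n_mirna, replace = TRUE,
                         prob = w / sum(w))

    decoy_pool <- unlist(decoys, use.names = FALSE)
    decoy_draw <- vapply(sample(decoy_pool, n_decoy, replace = TRUE),
                         function(ref) {
                           l <- sample(18:36, 1L)
                           s <- sample.int(nchar(ref) - l + 1L, 1L)
                           substr(ref, s, s + l - 1L)
                         }, character(1L), USE.NAMES = FALSE)

    other_draw <- character(0)
    if (n_other > 0) {
      lens <- sample(16:40, n_other, replace = TRUE)
      lens[1] <- 16L
      if (n_other > 1) lens[2] <- 40L
      other_draw <- random_rna(n_other, 16L)
      for (i in seq_len(n_other))
        other_draw[i] <- paste0(random_rna(1L, lens[i]), collapse = "")
    }

    tab <- table(c(mirna_draw, decoy_draw, other_draw))
    reads <- data.frame(sequence = names(tab),
                        abundance = as.integer(tab),
                        stringsAsFactors = FALSE)
    rownames(reads) <- NULL
    list(reads = reads, refsets = refsets)
  })
}

#' Simulate a qPCR Ct table with a known fold change
#'
#' Generates per-sample Ct values for one target assay and the reference
#' assay (U6 role) in two groups of `qpcr_n_per_group` samples. Group A
#' target Ct is shifted by `-log2(qpcr_fold_change)` relative to group B;
#' Gaussian noise of sd `qpcr_noise_sd` cycles is added to every measurement.
#'
#' @param config a [sim_config()] object.
#' @param assay_id target assay name.
#' @return data.frame with columns `sample_id`, `group`, `assay`, `ct`.
#' @export
simulate_qpcr <- function(config, assay_id = "miR-target") {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "simulate_qpcr"), {
    npg <- config$qpcr_n_per_group
    samples <- c(paste0("A", seq_len(npg)), paste0("B", seq_len(npg)))
    groups <- rep(c("A", "B"), each = npg)
    base_ref <- 18
    base_tgt <- 24
    shift <- ifelse(groups == "A", -log2(config$qpcr_fold_change), 0)
    noise <- function(n) rnorm(n, 0, config$qpcr_noise_sd)
    rbind(
      data.frame(sample_id = samples, group = groups, assay = assay_id,
                 ct = base_tgt + shift + noise(length(samples)),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = samples, group = groups, assay = "U6",
                 ct = base_ref + noise(length(samples)),
                 stringsAsFactors = FALSE))
  })
}
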