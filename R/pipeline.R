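#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()]:
#' simulation parameters (see [sim_config()]), analysis thresholds
#' (`alpha` 0.05, `lfc_min` 1, `score_min` 150, `energy_max` -20, `top_k`
#' 10, `n_perm` 999), stage toggles, the locus specification, and the output
#' directory. When `simulate` is `FALSE` the `paths` entries must point at
#' existing input files (annotation, counts, samples, miRNA and UTR FASTA,
#' GMT, and optionally a qPCR table).
#'
#' @param outdir output directory.
#' @param seed root RNG seed.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(outdir = "mirlocus_out", seed = 1L) {
  list(
    outdir = outdir,
    seed = seed,
    simulate = TRUE,
    sim = list(),                 # overrides for sim_config()
    locus = NULL,                 # list(name, chrom, start, end); required
                                  # when simulate = FALSE
    annotation_format = "bed",
    thresholds = list(alpha = 0.05, lfc_min = 1, score_min = 150,
                      energy_max = -20, top_k = 10, n_perm = 999),
    stages = list(profile = TRUE, qpcr = TRUE),
    paths = list(annotation = NULL, counts = NULL, samples = NULL,
                 mirna_fasta = NULL, utr_fasta = NULL, gmt = NULL,
                 qpcr = NULL)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unset keys fall back to [default_pipeline_config()].
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  modifyList(cfg, user)
}

validate_pipeline_config <- function(config) {
  th <- config$thresholds
  stopifnot(th$alpha > 0, th$alpha < 1, th$lfc_min >= 0, th$top_k >= 1,
            th$n_perm >= 1)
  if (!isTRUE(config$simulate)) {
    needed <- c("annotation", "counts", "samples", "mirna_fasta",
                "utr_fasta", "gmt")
    if (isTRUE(config$stages$qpcr)) needed <- c(needed, "qpcr")
    for (key in needed) {
      p <- config$paths[[key]]
      if (is.null(p) || !file.exists(p))
        stop("configuration error: input '", key, "' missing or not found (",
             p %||% "unset", ")")
    }
    if (is.null(config$locus))
      stop("configuration error: a locus (name, chrom, start, end) must be ",
         "supplied when simulate = FALSE")
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulate -> small-RNA profile -> differential
#' expression -> locus co-localization -> target prediction -> pathway
#' enrichment/recurrence -> qPCR, writing every result table under
#' `config$outdir` plus a machine-readable JSON run report. All randomness
#' derives from `config$seed`, so reruns with an identical configuration are
#' identical.
#'
#' @param config list from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @return The run report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  validate_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  th <- config$thresholds
  report <- list(package_version = as.character(utils::packageVersion("mirlocus")),
                 seed = config$seed, thresholds = th)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- inputs -------------------------------------------------------------
  truth <- NULL
  qpcr_tab <- NULL
  reads_sim <- NULL
  if (isTRUE(config$simulate)) {
    stage("simulate", {
      scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      ann_sim <- simulate_annotation(scfg)
      annotation <- ann_sim$annotation
      locus <- ann_sim$locus
      cts <- simulate_counts(annotation, scfg, locus)
      seqs <- simulate_sequences(annotation, scfg, cts$truth)
      gs <- simulate_genesets(scfg, seqs$target_truth)
      if (isTRUE(config$stages$profile))
        reads_sim <- simulate_reads(annotation, scfg, seqs$mirna_seqs)
      if (isTRUE(config$stages$qpcr)) qpcr_tab <- simulate_qpcr(scfg)
      counts <- cts$counts; groups <- cts$groups
      mirna_seqs <- seqs$mirna_seqs; utr_seqs <- seqs$utr_seqs
      genesets <- gs$genesets; universe <- gs$universe
      truth <- list(de = cts$truth, targets = seqs$target_truth,
                    pathway = gs$pathway_truth)
      write_annotation(annotation, out("annotation.bed"), "bed")
      write_counts(counts, out("counts.tsv"))
      write_samples(groups, out("samples.tsv"))
      write_fasta(mirna_seqs, out("mirna.fa"))
      write_fasta(utr_seqs, out("utr.fa"))
      write_gmt(genesets, out("genesets.gmt"))
      write.table(seqs$target_truth, out("target_truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(data.frame(mirna_id = names(cts$truth$de_truth),
                             truth = unname(cts$truth$de_truth)),
                  out("de_truth.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      if (!is.null(qpcr_tab)) write_qpcr(qpcr_tab, out("qpcr.tsv"))
    })
    report$truth <- list(pathway = truth$pathway,
                         n_up_planted = length(truth$de$up_ids),
                         n_down_planted = length(truth$de$down_ids))
  } else {
    stage("load_inputs", {
      annotation <- read_annotation(config$paths$annotation,
                                    config$annotation_format)
      counts <- read_counts(config$paths$counts)
      groups <- read_samples(config$paths$samples)
      mirna_seqs <- read_fasta(config$paths$mirna_fasta)
      utr_seqs <- read_fasta(config$paths$utr_fasta)
      genesets <- read_gmt(config$paths$gmt)
      universe <- names(utr_seqs)
      locus <- config$locus
      if (isTRUE(config$stages$qpcr))
        qpcr_tab <- read_qpcr(config$paths$qpcr)
    })
  }
  groups <- groups[colnames(counts)]

  # ---- small-RNA profile --------------------------------------------------
  if (isTRUE(config$stages$profile) && !is.null(reads_sim)) {
    stage("profile", {
      reads <- filter_by_length(reads_sim$reads)
      write.table(length_distribution(reads), out("length_distribution.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      annot <- annotate_by_priority(reads, reads_sim$refsets)
      write.table(annot$counts, out("read_categories.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      mirna_reads <- reads[annot$category == "miRNA", , drop = FALSE]
      write.table(first_base_preference(mirna_reads),
                  out("first_base_preference.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      report$profile <- list(
        n_unique_after_filter = nrow(reads),
        removed_abundance = attr(reads, "removed_abundance"),
        category_abundance = setNames(as.list(annot$counts$abundance),
                                      annot$counts$category))
    })
  }

  # ---- differential expression -------------------------------------------
  stage("de", {
    sf <- size_factors(counts)
    de <- nb_test(counts, sf, groups)
    called <- call_de(de, alpha = th$alpha, lfc_min = th$lfc_min)
    de <- called$results
    write.table(de, out("de_results.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    pca <- pca_samples(counts, sf)
    write.table(data.frame(sample_id = rownames(pca$scores), pca$scores,
                           group = groups[rownames(pca$scores)]),
                out("pca.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sample_correlation(counts, sf), out("correlation.tsv"),
                sep = "\t", quote = FALSE)
    cl <- cluster_patterns(counts, sf, k = 8,
                           seed = derive_seed(config$seed, "cluster_patterns"))
    write.table(data.frame(mirna_id = names(cl), cluster = unname(cl)),
                out("clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    chrdist <- chromosome_distribution(
      annotation, rowSums(sweep(counts, 2, sf, `/`)))
    write.table(chrdist, out("chromosome_distribution.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$de <- list(n_tested = nrow(de), n_up = length(called$up),
                      n_down = length(called$down),
                      size_factors = as.list(round(sf, 4)))
  })

  # ---- locus co-localization ---------------------------------------------
  stage("locus", {
    locus_stats <- list()
    for (dir in c("up", "down")) {
      ids <- called[[dir]]
      if (length(ids) == 0) next
      al <- assign_locus(ids, annotation, locus)
      locus_stats[[dir]] <- list(
        n_de = al$n_de, n_de_in_locus = al$n_de_in_locus,
        fraction_in_locus = al$fraction_in_locus,
        pct_of_locus_mirnas = locus_fraction_report(ids, annotation, locus),
        hypergeom_p = locus_hypergeom_test(ids, annotation, locus),
        permutation_p = locus_permutation_test(
          ids, annotation, locus, n_perm = th$n_perm,
          seed = derive_seed(config$seed, paste0("locus_perm_", dir)))$p)
      write.table(al$per_chrom, out(paste0("locus_per_chrom_", dir, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    de_all <- de[de$call != "ns", , drop = FALSE]
    if (nrow(de_all) >= 4) {
      fl <- assign_locus(de_all$mirna_id, annotation, locus)$flags
      if (sum(fl) >= 2 && sum(!fl) >= 2)
        locus_stats$effect_size_test <- compare_effect_sizes(
          de_all, fl, metric = "abs_log2fc")[c("statistic", "p")]
    }
    report$locus <- locus_stats
  })

  # ---- targets + enrichment ----------------------------------------------
  stage("targets_enrich", {
    up_ids <- called$up
    enrich_report <- list()
    if (length(up_ids) > 0) {
      hits <- predict_targets(mirna_seqs[up_ids], utr_seqs,
                              score_min = th$score_min,
                              energy_max = th$energy_max)
      write.table(hits, out("targets.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      toplists <- lapply(split(hits$gene_id, hits$mirna_id), function(genes)
        rank_top(hypergeom_enrich(unique(genes), genesets, universe),
                 top_k = th$top_k))
      rec <- recurrence(toplists)
      write.table(rec, out("recurrence.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      enrich_report <- list(
        n_target_pairs = sum(hits$best), n_mirna_groups = length(toplists),
        top_pathway = if (nrow(rec) > 0) rec$pathway[1] else NA,
        top_frequency = if (nrow(rec) > 0) rec$frequency[1] else 0)
    }
    report$enrich <- enrich_report
  })

  # ---- qPCR ---------------------------------------------------------------
  if (isTRUE(config$stages$qpcr) && !is.null(qpcr_tab)) {
    stage("qpcr", {
      rel <- ddct(qpcr_tab)
      write.table(rel, out("relative_expression.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      tests <- lapply(split(rel, rel$assay), function(d)
        group_compare(log2(d$rel_expr), d$group))
      write.table(
        data.frame(assay = names(tests),
                   method = vapply(tests, `[[`, "", "method"),
                   p = vapply(tests, `[[`, 1, "p"),
                   significant = vapply(tests, `[[`, TRUE, "significant")),
        out("qpcr_tests.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      report$qpcr <- lapply(tests, function(t)
        list(method = t$method, p = t$p, significant = t$significant))
    })
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
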