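# mirlocus

Tools for a recurring question in developmental small-RNA studies: when two
groups of samples (say newborn vs adult skin) are compared by miRNA-seq, do
the up-regulated miRNAs **co-localize in one genomic locus** — typically the
imprinted Dlk1–Gtl2 (Dlk1–Dio3) domain with its large clustered miRNA block
— and do their predicted targets **converge on one recurrent pathway**?

`mirlocus` implements the full analysis chain as a tested R package:

1. **Differential expression** — negative-binomial model
   (Var = μ + αμ²), median-of-ratios size factors, per-miRNA
   method-of-moments dispersion, Wald statistic referred to Student t
   (small-sample calibrated), Benjamini–Hochberg correction, calls at
   padj < 0.05 and |log₂FC| > 1; plus sample PCA, correlation and
   expression-pattern clustering.
2. **Locus co-localization** — in/out flags by ≥1 bp overlap with a named
   locus interval, per-chromosome DE counts, hypergeometric tail and a
   permutation null that resamples DE identity, and a Mann–Whitney
   comparison of effect sizes inside vs outside the locus.
3. **Target prediction** — canonical seed classes (8mer, 7mer-m8, 7mer-A1,
   6mer) on 3'UTRs, Smith–Waterman duplex re-scoring with a seed-weighted
   scoring matrix and a stacking-energy proxy, filtered at score > 150 and
   energy < −20 (both strict, both configurable), plus two-predictor
   intersection.
4. **Pathway recurrence** — per-miRNA hypergeometric enrichment over GMT
   gene sets, top-10 ranking (p, then enriched-gene count), and the
   cross-miRNA recurrence table ranking pathways by how many per-miRNA top
   lists contain them.
5. **qPCR validation** — 2^−ΔΔCt relative expression with Shapiro–Wilk
   screening and Welch/Wilcoxon comparison.
6. **Synthetic data** — a first-class generator that plants ground truth
   (a miRNA cluster at a locus, up-regulated miRNAs inside it, perfect
   target sites, one recurrent pathway, qPCR fold changes), so every stage
   is testable without sequencing data. Read-level QC summaries (length
   filter/distribution, priority annotation, first-base preference,
   per-chromosome abundance) are included.

See `vignettes/mirlocus-methods.Rmd` for the model details and every design
decision.

## Worked example

```r
library(mirlocus)
cfg <- default_pipeline_config(outdir = "mirlocus_out", seed = 42L)
rep <- run_pipeline(cfg)   # simulates a 150-miRNA, 5+5 study and analyses it

rep$de[c("n_up", "n_down")]
#> $n_up   [1] 32
#> $n_down [1] 48

str(rep$locus$up)
#> $ n_de               : int 32
#> $ n_de_in_locus      : int 32
#> $ fraction_in_locus  : num 1
#> $ pct_of_locus_mirnas: num 31.7
#> $ hypergeom_p        : num 4.52e-07
#> $ permutation_p      : num 0.001

rep$enrich[c("top_pathway", "top_frequency", "n_mirna_groups")]
#> $top_pathway    [1] "PW020"
#> $top_frequency  [1] 32
#> $n_mirna_groups [1] 32

rep$truth$pathway
#> [1] "PW020"

rep$qpcr[["miR-target"]]$p
#> [1] 0.0002067188
```

Reading the numbers: all 32 recovered up-regulated miRNAs fall inside the
planted locus (`fraction_in_locus = 1`), they make up 31.7% of the 101
miRNAs annotated there, and both nulls reject co-localization by chance
(hypergeometric p ≈ 5e-7; permutation p = 0.001, the minimum attainable at
999 permutations). The planted pathway PW020 tops the recurrence table,
appearing in all 32 per-miRNA top-10 lists, and the simulated 8-fold qPCR
difference is significant. Result tables (`de_results.tsv`,
`recurrence.tsv`, `targets.tsv`, ...) and a machine-readable `report.json`
are written to `outdir`; reruns with the same config and seed are
byte-identical.

A command-line driver with the same behaviour ships in
`inst/cli/mirlocus.R`:

```sh
Rscript inst/cli/mirlocus.R run --outdir out --seed 42
Rscript inst/cli/mirlocus.R run --config my_config.yaml
```

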