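---
title: "mirlocus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirlocus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlocus)
```

## The analysis this package implements

Developmental skin and fur phenotypes in sheep (and other mammals) have been
linked to a block of microRNAs transcribed from the imprinted Dlk1–Gtl2
(Dlk1–Dio3) domain. A typical study design compares small-RNA sequencing of
two groups — say newborn-like ("A") and adult-like ("B") skin — and asks
three questions in sequence:

1. which miRNAs are differentially expressed between the groups,
2. whether the up-regulated miRNAs co-localize in one genomic locus rather
   than scattering over the genome, and
3. whether their predicted targets converge on one recurrent signaling
   pathway.

`mirlocus` makes that chain computable and testable end to end:
`run_pipeline()` goes from a count matrix (or a fully synthetic study) to a
JSON report containing the DE calls, the locus co-localization statistics,
the target predictions, the pathway recurrence table and a qPCR validation
analysis.

## Differential expression

Counts are modelled as negative binomial with `Var = mu + alpha * mu^2`.
Normalization uses median-of-ratios size factors: for every miRNA with
nonzero counts in all samples, each sample's count is divided by the miRNA's
geometric mean, and the sample's factor is the median of those ratios.

Per miRNA, `nb_test()` estimates the dispersion `alpha` by method of moments
pooled across the two groups (floored at 1e-8) and forms a Wald statistic
`log2fc / se`, with the delta-method standard error of the log ratio of
group means under the NB model. Because the normalized counts are
heteroscedastic across samples (`Var(y_s) = q / sf_s + alpha * q^2`), the
Poisson part of the variance uses the group mean of `1 / sf_s`.

Two deliberate choices:

* **No dispersion shrinkage across miRNAs.** Unlike DESeq2 or edgeR, every
  miRNA is treated independently. This keeps the estimator transparent and
  is sufficient here because the package's claims are calibrated against
  synthetic truth, not against matching another tool's output.
* **Student-t reference, not normal.** With 5 + 5 samples the plugin
  variance carries roughly 8 degrees of freedom; referring the Wald
  statistic to N(0,1) rejects true nulls at about 8% when the nominal level
  is 5% (measured over repeated null simulations at the package's default
  scale). Referring it to t with `n - 2` df restores the nominal level
  (measured type-I error about 4.7%, stable across dispersions 0.05–0.2 and
  3–5 samples per group). The t reference is the package's small-sample
  calibration of the asymptotic Wald test; the acceptance suite re-measures
  the level on every run.

DE calls use the conventional strict thresholds: adjusted P < 0.05
(Benjamini–Hochberg step-up, implemented in `bh_adjust()` and cross-checked
against an independent implementation in the tests) and |log2 fold change|
> 1. The fold-change direction is group A over group B. A +0.5 pseudocount
on the normalized group means keeps log fold changes finite for zero-count
groups without affecting symmetric cases (duplicated columns give exactly 0).

## Locus co-localization

`assign_locus()` flags a miRNA as "in locus" iff it lies on the locus
chromosome and its interval overlaps the locus interval by at least 1 bp.
Coordinates are 0-based half-open internally; BED input is used as-is and
GFF3 is converted, so the same feature is flagged identically from either
format. Strand is ignored: the locus is a genomic region, not a stranded
transcript. The locus itself must always be user-supplied (name,
chromosome, interval) — real coordinates are never hard-coded.

Two nulls quantify over-representation:

* `locus_hypergeom_test()` – the upper hypergeometric tail P(X >= k) with
  N annotated miRNAs, K inside the locus and n DE calls;
* `locus_permutation_test()` – resamples the *identity* of the DE set
  (which miRNAs are DE), not their positions. This preserves the genome's
  clustered annotation structure, which is exactly the confounder of
  interest; p = (1 + #{permuted fraction >= observed}) / (n_perm + 1), so
  the smallest attainable p is 1/(n_perm + 1).

Effect sizes inside vs outside the locus are compared by a two-sided
Mann–Whitney U test on |log2fc| or -log10(padj); a rank test avoids any
normality assumption on fold-change estimates.

## Target prediction

Only 3'UTRs are scanned. Candidate sites come from the canonical seed
classes, defined on miRNA positions 2–8 from the 5' end: 8mer (match to
nt 2–8 plus an A opposite nt 1), 7mer-m8 (nt 2–8), 7mer-A1 (nt 2–7 plus
A), 6mer (nt 2–7). The scanner reports all sites, including overlapping
occurrences, and is verified against a brute-force enumeration in the test
suite.

Each candidate site is re-scored by a Smith–Waterman local alignment of the
reversed miRNA against the surrounding UTR window (affine gaps): match +5,
G:U wobble +2, mismatch -3, gap open -8, gap extend -2. Pairing scores at
seed positions 2–8 are multiplied by 4 — the scale factor the miRanda
program applies to its 5' seed region — so a perfect complement of a 22-mer
scores 15·5 + 7·20 = 215. A duplex energy proxy sums stack terms over
adjacent paired positions: -3 kcal/mol for a G:C/G:C stack, -1 for
A:U/G:U-only stacks, -2 for mixed stacks.

Sites are kept iff score > 150 **and** energy < -20, both strict — the
thresholds conventionally used with miRanda output. Important honesty note:
these scoring constants are *artifact-defined*; the package does not
reproduce miRanda's full scoring model, and numeric agreement with miRanda
v3.3a is explicitly not claimed. The thresholds are configurable precisely
because the scales differ. The seed multiplier of 4 (rather than 2) was
chosen so that full-length perfect-complement sites — the planted ground
truth of the synthetic data — clear the strict score filter: with a
multiplier of 2 a perfect 22-mer site would score 145 and no canonical
miRNA could ever pass score > 150, which would make the documented
workflow vacuous.

`intersect_predictions()` implements the common two-predictor consensus
step: hits are kept only when the (miRNA, gene) pair is called by both
predictors. The `TargetHit` schema carries an `alignment-only` class level
for hits supplied by external tools without a canonical seed; the internal
seed-gated scanner never produces it.

## Enrichment and pathway recurrence

Per miRNA, predicted target genes are tested against each gene set with the
upper hypergeometric tail; P-values are BH-adjusted within the miRNA. The
background universe defaults to all genes with a UTR in the input, and is
overridable. This is a transparent, offline replacement for web-service
enrichment (DAVID's EASE score is a modified Fisher test; the plain
hypergeometric is the textbook equivalent).

`rank_top()` orders pathways by ascending p, ties broken by more enriched
genes, then lexicographic id, and keeps the top 10. Pathways with zero
enriched genes are excluded (`min_k = 1`): enrichment tools only report
pathways actually containing input genes, and including k = 0 rows would
let lexicographic tie-breaking among p = 1 pathways flood every top list.

`recurrence()` counts, for each pathway, how many per-miRNA top-10 lists
contain it. The recurrence *fraction* divides by the number of miRNA groups
analyzed; frequency and denominator are both reported because published
percentages on this statistic are occasionally inconsistent with their own
denominators.

## qPCR validation

`ddct()` implements 2^-ddCt: technical replicates are averaged, dCt =
Ct(target) - Ct(reference assay, the U6 role) per sample, ddCt subtracts
the calibrator group's mean dCt, relative expression is 2^-ddCt. Per-sample
pairing (rather than group-mean differencing) is used at the dCt stage; the
calibrator group's relative expression has geometric mean 1 by
construction.

`group_compare()` screens each group with Shapiro–Wilk (P > 0.05 read as
normal) and compares the groups with a two-sided Welch t-test when both
pass. The non-normal fallback is a Wilcoxon rank-sum test — but only when
both groups have at least 4 values. At n = 3 per group an exact rank test
cannot reach P < 0.05 at all (its smallest two-sided p is 0.1), so the
package uses the Welch test regardless and labels the result
`welch_t_nonnormal`. Relative expression should be compared on the log2
scale (the pipeline passes `log2(rel_expr)`), where multiplicative qPCR
noise is closest to Gaussian; testing raw fold ratios with 3 samples per
group is badly underpowered and was measured to cost ~20 points of power at
an 8-fold effect.

## The synthetic-data generator

`sim_config()` fixes the stated world; its defaults mirror the scale of the
motivating study design: 150 annotated miRNAs, 101 of them in one cluster
on chr18 (a Dlk1–Gtl2 stand-in), 32 planted up-regulated miRNAs all inside
the cluster, 48 planted down-regulated miRNAs scattered elsewhere, planted
log2 fold changes ±2, NB dispersion 0.05, 5 + 5 samples, baseline means
log-uniform over 10^[1,3], per-sample size factors log-uniform in [0.5, 2].
Values the design leaves open were chosen once as field-plausible: 200
genes with 300-nt UTRs, 20 pathways of 10–40 genes, mature miRNAs of 21–22
nt with first-base U probability 0.6, read sets of 50,000 reads with 15%
decoy (rRNA/tRNA/snRNA/snoRNA fragments) and 5% unclassifiable mass, qPCR
noise 0.25 cycles with 3 biological replicates per group.

Planted target sites are full-length perfect complements of the mature
miRNA inserted into a UTR, which guarantees passage of the score/energy
filters independent of scoring details; mature sequences are additionally
forced to carry at least one G or C after position 1, because an all-A:U
21-mer duplex would sit exactly at the -20 energy boundary and fail the
strict filter. All randomness flows from one root seed through
`derive_seed(seed, operation_name)`, so any stage can be re-run in
isolation and reproduce the pipeline byte for byte.

What the generator does *not* emulate — and hence what a green test does
not establish: real miRNA sequence composition and family structure,
alignment ambiguity of multi-mapping reads, adapter/quality artifacts,
genome-wide annotation biases, correlated pathway membership, or
amplification-efficiency differences in qPCR. Green acceptance tests
establish that the pipeline's statistics are calibrated and recover planted
truth at the study's scale; they say nothing about any particular real
dataset.

## Numerical and degenerate-input choices

* BH adjustment clamps to [p, 1]; empty input returns empty output.
* All-zero miRNAs are excluded from size-factor geometric means, reported
  with p = 1, log2fc = 0 and flagged.
* PCA is computed on log2(normalized + 1), miRNA-centered; component signs
  are fixed by forcing the largest-magnitude loading positive; a constant
  matrix raises a zero-variance error.
* k-means pattern clustering z-scores each miRNA profile (zero-variance
  profiles become flat zeros) and fixes the RNG seed; `k = 1` short-circuits.
* The permutation p-value uses the add-one estimator and therefore can never
  be 0.
* An empty locus (no annotated miRNAs inside) makes the locus-fraction
  report an explicit error rather than a division by zero.
* Hypergeometric tails are computed with `phyper(k - 1, ...)`, verified
  against exhaustive enumeration for N <= 25.

## Known limitations

* The DE test has no dispersion moderation; at very low counts (< ~10 per
  group) its power drops faster than DESeq2's would.
* Target scoring is a calibrated stand-in: ranks are meaningful within this
  package, absolute scores are not comparable to miRanda/TargetScan output.
* The read-annotation stage uses exact substring membership, not alignment;
  reads with sequencing errors would fall into "other".
* Enrichment treats gene sets as flat, unrelated sets; no hierarchy or
  overlap correction across pathways, and no multiple-testing across miRNAs
  (the recurrence statistic is descriptive, as in the motivating workflow).
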