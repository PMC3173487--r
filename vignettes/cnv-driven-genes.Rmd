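---
title: "Finding CNV-driven genes and validating them against survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding CNV-driven genes and validating them against survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdrive)
```

## The problem

Tumor genomes accumulate copy-number variations (CNVs): whole arms or focal
regions drift away from the diploid baseline of two copies. When a region is
recurrently amplified or deleted across a cohort, the genes inside it are
candidate oncogenes or tumor suppressors — but only a minority of them
actually change their expression in response to the dosage change. cnvdrive
implements a complete desk-scale pipeline for the integrated analysis that
separates those *CNV-driven* genes from passengers, and for testing whether
gene sets built from them predict patient survival:

1. **Segmentation** of per-pair marker tracks into copy-number segments.
2. **Recurrent CNVR calling** at a cohort frequency threshold.
3. **CNV-expression integration**: per-gene grouping of patients by
   copy-number status, Welch t-tests under Bonferroni control, and a
   concordance filter.
4. **Gene-set enrichment** of the resulting driver list.
5. **Survival validation** of gene sets by a Cox-score median split with a
   random-gene-set empirical null.

A seeded synthetic-cohort generator reproduces the statistical structure the
analysis assumes, so every stage is testable end to end with no external
data.

## Segmentation model

The input to segmentation is one marker track per tumor/normal pair:
absolute copy-number estimates (diploid = 2) at ordered genomic positions,
derived upstream as `2 * 2^(log2 tumor/normal ratio)`. Because each tumor is
referenced against its own matched normal, germline copy-number
polymorphisms cancel and no population reference filtering is needed.

We segment by **recursive binary splitting**. For a stretch of markers, every
admissible breakpoint is scored with the unequal-variance (Welch) t statistic
between the two flanks; the |t|-maximizing breakpoint is accepted when all
three criteria hold:

* both flanks contain at least `min_markers` markers (default **100**),
* the two-sided Welch p-value is at most `split_p` (default **0.001**),
* the signal-to-noise ratio — |Δmean| divided by the pooled within-flank
  standard deviation — is at least `snr` (default **0.3**).

Splitting recurses until no admissible breakpoint remains. A segment is
called **amplified** when its mean copy number exceeds 2.3 and **deleted**
below 1.7 (`min_cn_change = 0.3` around the diploid baseline); the
boundaries are strict, so a segment at exactly 2.3 stays neutral.

Numerical choices: candidate-flank variances are floored at 1e-12 so
noiseless fixtures do not divide by zero; ties in |t| resolve to the
leftmost candidate; the p ≤ 0.001 rule is applied to the breakpoint test
(one reading of an under-specified criterion — the alternative, a
segment-versus-genome test, is not implemented). We read the p-value
criterion per breakpoint rather than correcting for the scan over
candidates; in practice the SNR and the variant-call thresholds dominate
false positive control — under pure diploid noise (sd 0.05, 10,000 markers)
spurious *variant* segments essentially never occur, which the test suite
checks over 100 seeds.

## Recurrent CNVRs and gene mapping

Per-sample variant segments are stacked into per-direction frequency tracks
on bins delimited by the union of all segment boundaries (every boundary is
a marker position, so this is marker-resolution counting). A copy-number
variable region (CNVR) is a maximal run of bins whose carrier count reaches
`ceiling(threshold * n)` — at the default **30%** threshold and n = 42 that
is 13 samples. Amplification and deletion CNVRs are called independently
and may overlap. Genes join a CNVR on *any* overlap (≥ 1 base, half-open
coordinates) — the most permissive reading; a gene overlapping CNVRs of
both directions is analyzed once per direction.

## CNV-driven gene identification

For each CNVR gene and each patient, copy-number status is `varied` when
the gene overlaps a variant segment matching the CNVR direction, `opposite`
when it overlaps only variant segments of the other direction (such
patients are excluded from both groups), and `neutral` otherwise.

The default (`paired`) mode compares tumor-tissue expression of varied
patients against normal-tissue expression of neutral patients with a Welch
t-test; the `tumor_only` mode compares tumor expression of varied versus
neutral patients, for cohorts without adjacent normals. The two modes agree
in direction whenever the copy-number-independent tumor/normal baseline
shift is zero, which the tests verify on synthetic data.

Significance uses Bonferroni control at `0.05 / G`, where `G` counts *all*
(gene, CNVR) rows including untestable ones — the conservative choice that
at genome scale (about 5,000 CNVR genes) drives the per-test threshold to
1e-5 or below. Significant genes are then **concordance-filtered**: only
amplification-with-up-regulation or deletion-with-down-regulation survive.
Exact mean ties break to "up" — irrelevant in continuous data, but it makes
fixtures deterministic.

Two descriptive outputs accompany the driver list: a **Z-value** matrix
(per gene, subtract the median intensity of the normal tissues of
copy-number-neutral patients, divide by the neutral-sample SD) for
clustering-style displays, and per-gene **Pearson correlations** between
gene-level copy number (segment means weighted by overlapped gene length)
and tumor expression, reported for drivers, all CNVR genes and the whole
genome. The Z-value reference is ambiguous in the field's usage (median "in
normal tissue" versus SD "among neutral samples"); we take the median over
normal tissues of neutral patients and, by default, the SD over the same
normal-tissue values, with `sd_tissue = "both"` available to pool the
tumor and normal values of neutral patients.

## Enrichment

The driver list is tested against user-supplied gene sets (GMT) with
one-sided Fisher's exact tests over the platform universe — all genes in
the annotation, the natural background when the true background of a
proprietary pathway tool is unknowable. No multiplicity correction is
applied across sets; sets are flagged at raw −log10 p > 2.0, matching the
convention of canonical-pathway tables.

## Survival validation

For a gene set and an expression-plus-survival cohort:

1. Standardize each gene across patients by the **Z-score** method. We fix
   the population-SD convention (divisor n); the choice is arbitrary but
   must be fixed, and it matches the generator's survival model exactly.
2. Fit a Cox proportional-hazards model (Efron ties) of survival on the
   set's standardized expression; each patient's **Cox regression score**
   is the linear predictor `S_i = sum_j beta_j z_ij`.
3. **Median split**: patients with scores strictly above the cohort median
   form "High Score", the rest "Low Score" (ties and the median itself go
   Low, making |High| ≤ |Low| deterministic).
4. Compare the groups with the unweighted **log-rank** test.
5. Build a null by repeating the identical procedure — including the Cox
   refit, the only reading that keeps the null exchangeable — on
   `n_iter` random gene sets of the same size drawn uniformly without
   replacement from the pool (all genes surviving zero-SD filtering). The
   **empirical p** is the add-one rank `(1 + #{null <= observed}) /
   (n_iter + 1)`, which cannot reach zero and resolves to 1e-5 at the
   default `n_iter = 100,000`. Non-convergent null fits (diverging or
   non-finite coefficients) are resampled and counted; more than 1% aborts.

Runtime note: the null loop calls `survival::coxph.fit` directly rather
than the `coxph` formula interface, whose model-frame construction
dominates at 10^5 iterations; a test asserts both give identical
coefficients.

## The synthetic cohort

`cohort_config()` defaults encode the study conditions the pipeline is
designed for: **42 tumor/normal pairs**; six 40-Mb chromosomes with markers
every 25 kb; three broad amplifications (chr1, chr5, chr7) and three focal
deletions (chr3, chr8, chr17) at carrier frequencies 0.40–0.60, with the
most frequent events at 60% of samples; **12%** of CNVR genes coupled to
copy number, of which **22%** with negative coupling; coupling strength
gamma = 0.8 expression-SD per copy; and survival drawn from an exponential
proportional-hazards model with log-hazard 0.5 per gene on a designated
7-gene active set, censored uniformly over 6–120 months.

The planted events are *driver-like*: high-level amplifications (+2.5
copies, to copy number 4.5) and deep deletions (−1.9, to 0.1 — near-total
loss with a small residue, as bulk tissue reads it). This is a deliberate
power choice made at design time: with gamma fixed at 0.8 SD per copy and
Bonferroni control over ~170 CNVR genes at n = 42, an a-priori Welch power
calculation shows single-copy changes are undetectable (|ΔCN| ≈ 2 is
required for ~90% power), so a recovery benchmark planting hemizygous
losses would measure nothing but its own lack of power. The corollary is a
known limitation: genes under one-copy loss are systematically underpowered
at this design size, in the synthetic benchmark and in any comparable real
cohort.

Carrier assignment is deterministic by default — exactly
`ceiling(freq * n)` seed-shuffled carriers — so frequency-threshold tests
are exact; a Bernoulli mode is available. Expression is generated directly
on a continuous log-intensity scale
(`baseline + tumor_effect + gamma * (CN - 2) + noise`); there is no
probe-level microarray noise model, no tumor-purity gradient, no
normal-tissue contamination and no batch effects. Passing the recovery
tests therefore demonstrates the statistical machinery under the model's
own assumptions, not robustness to those real-data complications.

Everything is driven by one integer seed; identical configurations give
bit-identical cohorts, and the generator restores the caller's RNG state.

## Problem sizes used by the checks

The test suite exercises the pipeline at the sizes the analyses were
designed for: driver-gene recovery averages 50 default cohorts
(sensitivity ≥ 0.90 for positively coupled planted genes, false flags
≤ 5% of uncoupled CNVR genes); Cox coefficient recovery pools Wald
coverage over 100 validation-sized cohorts (n = 110, the scale of typical
validation series); null calibration checks Kolmogorov–Smirnov uniformity
of the empirical p over 200 random gene sets at 500 null iterations each;
and the power check requires empirical p < 0.05 in at least 80% of 50
seeds at planted log-hazard 0.5. The analysis drivers under `analysis/`
run the same stages with the null reduced to 1,000 iterations.

## Known limitations

* The segmentation operationalizes published segment *criteria*; it is not
  a reimplementation of any vendor algorithm, and on real arrays its exact
  breakpoints will differ from tools with different scan statistics.
* Gene-level copy number is a length-weighted segment-mean average; genes
  straddling a breakpoint inherit a blended value.
* The survival validation fits expression-only Cox models; no clinical
  covariate adjustment is offered.
* Empirical p-values from sets tested on the same cohort share the cohort's
  event times and are therefore not independent across sets.
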