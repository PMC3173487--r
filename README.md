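# cnvdrive

Integrated copy-number / gene-expression analysis for paired tumor-normal
cohorts: find recurrently copy-number-variable regions (CNVRs), identify the
genes whose expression is *driven* by those copy-number changes, and test
whether gene sets built from them predict patient survival.

## Who this is for

Cancer genomics analysts with paired tumor/normal copy-number marker tracks
(or pre-segmented SEG files), a matching expression matrix, gene annotations
(BED), gene sets (GMT) and clinical survival tables. The package also ships
a seeded synthetic-cohort generator that reproduces the statistical
structure such a study assumes — 42 tumor/normal pairs, recurrent
amplifications and deletions at 30–60% carrier frequency, ~12% of CNVR genes
coupled to copy number, survival tied to a designated pathway — so the whole
pipeline runs and is tested without any download.

## The method

1. **Segmentation.** Per pair, marker-level copy number (diploid = 2) is
   segmented by recursive binary splitting: a breakpoint maximizes the
   Welch t statistic between its flanks and is accepted only if both flanks
   have ≥ 100 markers, the two-sided p ≤ 0.001 and the signal-to-noise
   ratio |Δmean| / pooled within-flank SD ≥ 0.3. Segments above copy number
   2.3 are amplified, below 1.7 deleted.
2. **Recurrent CNVRs.** Per-direction carrier-frequency tracks at marker
   resolution; maximal runs with ≥ ⌈0.30·n⌉ carriers (13 of 42) become
   CNVRs, and genes join by any overlap.
3. **CNV-driven genes.** Patients are grouped per gene into copy-number
   *varied* vs *neutral*; a Welch t-test (tumor expression of varied vs
   normal expression of neutral patients, or tumor-only) under Bonferroni
   control 0.05/G over all G CNVR genes, followed by a concordance filter
   (amplification∧up or deletion∧down). Per-gene Pearson correlations
   between copy number and tumor expression profile the result.
4. **Enrichment.** One-sided Fisher's exact tests of the driver list
   against GMT gene sets; significant at raw −log10 p > 2.0.
5. **Survival validation.** Per gene set: Z-score standardization, Cox
   proportional-hazards scoring S_i = Σ_j β_j z_ij, median split into
   High/Low Score groups, log-rank comparison, and an empirical p ranking
   the observed log-rank p in a null of random same-size gene sets
   re-fitted identically (default 100,000 iterations; add-one convention).

## Worked example

```r
library(cnvdrive)

co <- generate_cohort(cohort_config())          # default 42-pair cohort
pl <- run_pipeline(co, n_iter = 200, seed = 7)  # survival null: 200 draws
```

The run logs each stage (counts are for the default seed):

```
segmenting 42 tumor/normal pairs
  127 variant segments called
step 1: 6 recurrent CNVRs at the 30% threshold (>= 13 samples)
step 2: 168 genes mapped into CNVRs
step 3: 19 differentially expressed genes (Bonferroni 0.05/168)
step 4: 15 concordant CNV-driven genes (4 discordant dropped)
enrichment: 1 of 8 sets significant at -log10 p > 2
survival: set 'active_pathway' observed log-rank p = 1.84e-06, empirical p = 0.004975
```

Reading it: all six planted CNVRs are recovered; 168 genes lie inside them;
19 pass the Bonferroni-controlled Welch test of which 15 change expression
in the same direction as their copy number — those are the CNV-driven
genes. The designated survival-active pathway beats every one of its random
null sets (empirical p ≈ 1/201), while decoy sets come out flat. Comparing
against the generator's truth:

```r
recovery_stats(pl, co$truth)
#> $sensitivity      0.9375   (15/16 planted positively coupled genes)
#> $false_flag_rate  0        (0 of 148 uncoupled CNVR genes flagged)
```

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (`01_simulate.R` … `06_survival.R`), writing tables under
`results/`.

## Documentation

The methods vignette (`vignettes/cnv-driven-genes.Rmd`) describes the model
and its assumptions, all tunable thresholds with their defaults, what the
synthetic generator does and does not emulate, and the package's design
decisions.
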