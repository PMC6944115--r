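# gliomastrat

Survival-driven marker stratification and immune profiling for tumour
cohorts, built around a recurring observation in high-grade glioma: the
tumours expressing the highest level of a marker can form a group that
contains no long survivors. The package provides the whole analysis chain
as composable, tested R functions:

* **Digital IHC quantification** — H-score
  (`HSCORE = Σ i·Pᵢ` over pixel intensity classes 0–3, range 0–300),
  percent strongly labelled pixels, and binary mutation calls from
  mutation-specific staining.
* **Stratification scans** — a dual cutoff search that, for every
  admissible marker split, derives the survival cutoff as the longest
  survival of the marker-high group, builds the (hi/lo × short/long
  survivor) table with censored-below-cutoff samples excluded, and picks
  the split minimising the two-sided Fisher exact P; plus a constrained
  log-rank scan (rank composite of P, group balance, and median survival
  difference) and survival-time cutoff scans for externally fixed groups.
* **Survival statistics** — Kaplan–Meier product-limit curves, median
  survival, the two-group log-rank test, two-sided Fisher's exact test,
  Pearson chi-square, Mann–Whitney and Kruskal–Wallis + Dunn comparisons.
* **Moderated differential expression** — empirical-Bayes variance
  moderation (posterior variance `(d₀s₀² + d s²)/(d₀ + d)`, moderated t on
  `d₀ + d` df), Benjamini–Hochberg FDR, detection/collapse/reference-gene
  filters, hypergeometric over-representation analysis.
* **Prognostic signature construction** — a second-round threshold-grid
  search over upregulated genes scored per sample and dichotomised at a
  fixed enrichment cutoff (−0.05), selected by Fisher separation of
  marker-high tumours from long survivors.
* **Single-sample enrichment scores** — a rank-based weighted running-sum
  statistic bounded in [−1, 1], invariant to monotone per-gene transforms,
  with molecular-subtype assignment and correlation-distance (UPGMA)
  clustering.
* **Purity-corrected deconvolution** — immune/stromal infiltrate scores,
  tumour purity, non-negative least-squares cell-type fractions against a
  reference signature matrix, `(1 − purity)` correction, and
  marker–fraction correlations.
* **A synthetic cohort generator** with fully recorded ground truth, so
  every stage above is exercised end-to-end with no external data.

Results come back as tibbles or small S3 objects with `tidy()`,
`glance()`, and `autoplot()` methods.

## Worked example

Generate a cohort with a planted marker-high group (30% of 76 samples, no
survivor past 1.8 years) and recover it:

```r
library(gliomastrat)

co  <- generate_cohort(cohort_config(seed = 42))
d   <- dplyr::inner_join(co$clinical, co$marker[, c("sample_id", "value")],
                         by = "sample_id")
res <- dual_cutoff_fisher_scan(d, marker = "value")
res
#> <strat_result: dual_fisher scan on marker `value`>
#>   expression cutoff: 165.7  (hi n=23, lo n=53)
#>   survival cutoff:   1.732 years (10 censored sample(s) below it excluded)
#>   Fisher exact P:    0.005974 (minimised over 61 candidate splits; selection-biased)
#>   log-rank P:        0.02387

res$table
#>      survival
#> group short long
#>    hi    21    0
#>    lo    32   13
```

The scan found the 23-sample marker-high group (exactly the planted one —
compare `tidy(res)` with `co$truth$hi_samples`), derived the survival
cutoff 1.73 years as the longest high-group survival, and excluded the 10
censored samples below it from the table: all 13 long survivors sit in the
marker-low group. The reported P is a minimum over 61 candidate splits and
is flagged as selection-biased accordingly. `autoplot(res)` draws the
marker-versus-survival quadrant plot with both cutoffs.

A published 2×2 worked example reproduces directly:

```r
fisher_exact_two_sided(matrix(c(10, 2, 30, 27), nrow = 2))
#> [1] 0.06044035   # 0.0604 to three significant figures
```

Downstream, `moderated_de()` + `build_signature()` compress the high-group
program into a gene signature, `sample_enrichment_scores()` scores any
cohort for it, and `deconvolve()` + `purity_correct()` estimate which cell
types fill the non-tumour compartment. `run_pipeline()` chains all stages
from files on disk and writes a manifest so a run is reproducible from its
own outputs.

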