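---
title: "From pooled shRNA dropout screens to prognostic candidate genes: methods and design notes"
author: "crcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pooled shRNA dropout screens to prognostic candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The analysis this package implements

A pooled shRNA proliferation screen infects a cancer cell line with a
library of knockdown reagents (typically ~5 shRNAs per gene across tens of
thousands of genes, at low multiplicity of infection so each cell carries
one reagent), sequences the integrated hairpins at a baseline time point
("day 0") and again after a growth period ("day 4"), and asks which genes'
reagents changed in relative abundance. An shRNA that *drops out* by day 4
silenced a gene the cells need to proliferate; concordant dropout of
several independent shRNAs against the same gene is the evidence unit.

`crcscreen` implements that computation and the analyses that typically
surround it in a candidate-gene study:

1. **Screen statistics** (`cpm_normalize`, `shrna_test`, `filter_shrnas`,
   `aggregate_genes`): counts-per-million normalisation, a per-shRNA
   day-0-vs-day-4 test, a three-criterion filter, and gene-level
   aggregation into depleted (growth-promoting) / enriched
   (growth-inhibiting) calls.
2. **Paired tumour/normal differential expression** (`paired_de`,
   `bh_fdr`) for matched patient tissue profiles.
3. **Integration** (`direction_consistent_candidates`, `rank_candidates`):
   keep genes whose screen phenotype and tissue expression change point the
   same way, rank by expression FDR.
4. **GSEA** (`rank_metric`, `enrichment_score`,
   `permutation_significance`) of knockdown-vs-control transcriptomes.
5. **Prognosis** (`km_estimate`, `logrank_test`, `roc_cutoff`,
   `dichotomize_and_compare`, `pearson_correlation`) for
   biomarker-dichotomised survival.
6. **Assay formulas** (`ihc_final_score`, `ddct_fold_change`,
   `chip_percent_input`, `dual_luciferase_ratio`, `tumor_volume`).
7. **Simulators** (`simulate_*`) producing every input with recorded
   ground truth, so each stage can be validated by planted-truth recovery.

## The screen model and its three filter criteria

Counts are normalised per sample to counts per million:
$\mathrm{CPM}_{is} = 10^6 \, c_{is} / \sum_j c_{js}$. An shRNA enters the
hit set when

1. its **mean day-0 abundance** is strictly greater than 25 CPM — reagents
   that were already nearly absent at baseline cannot show dropout;
2. its day-0 vs day-4 difference has **P strictly below 0.05**; and
3. at least **3 shRNAs against the same gene** satisfy (1) and (2).

Both thresholds are deliberately strict inequalities; boundary values
(exactly 25 CPM, exactly P = 0.05) are excluded.

The per-shRNA test is a two-sided Welch *t*-test on
$\log_2(\mathrm{CPM} + 0.5)$ replicate values. Screens of this design
rarely report which test was used; Welch on pseudocounted log-CPM is a
robust small-sample default, and the 0.5 pseudocount avoids $\log 0$ while
biasing low-abundance fold changes toward zero (conservative). Criterion
(3) is interpreted as *three shRNAs passing criteria (1) and (2)*, not
three in the library — the reading under which it actually filters.
Degenerate rows are resolved explicitly: both groups constant and equal
gives $P = 1$; both constant but different gives the smallest
representable double and a `zero_variance` flag, never `NaN`.

Gene direction is the sign of the median passing log2 fold change; an
exact-zero median leaves the gene unreported (counted in the attached
log). Per-gene evidence is combined by Stouffer's method on one-sided
p-values oriented by the gene's direction, so a discordant shRNA actively
weakens the combined call rather than being ignored.

## Integration and ranking

A gene depleted in the screen promoted growth; if it is also *upregulated*
in tumours it is a coherent oncogene candidate. Symmetrically
enriched-and-downregulated genes are coherent growth suppressors. The
candidate set is exactly this 2×2 predicate applied to the merged tables.
Ranking uses the differential-expression q-value by default (the aberrant
expression analysis), with `rank_by = "screen"` or `"product"` preserved
as alternatives; ties break by larger |log2FC|, then gene symbol, so ranks
are total and reproducible.

## GSEA

The enrichment score is the classic weighted Kolmogorov–Smirnov running
sum: walking the ranked list, hits add $|r|^p / \sum_{hits}|r|^p$
(weight $p = 1$ by default), misses subtract $1/(N - N_{hits})$, and the
ES is the signed extremum; at $p = 0$ this is exactly the two-sample KS
statistic on hit positions, which the tests exploit as an oracle.
Significance uses **gene-label permutation** (random sets of matched
size): knockdown experiments with 2–3 replicates per arm cannot support
phenotype permutation. NES divides the ES by the mean magnitude of
same-sign null scores; the nominal p is add-one corrected; FDR q compares
each NES against the pooled sign-matched null NES distribution. The whole
procedure is deterministic under its `seed` argument.

## Survival and biomarker cutoff

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package (the field standard), exposed through tidy step tables;
the test suite re-derives both from the product-limit definition and the
O/E/V accumulation to guard the wrapper's conventions (events precede
censorings at tied times). The ROC cutoff maximises the Youden index over
all midpoints between consecutive distinct marker values, ties going to
the lowest cutoff; the dichotomisation outcome is the event indicator at
end of follow-up — the simplest defensible choice when the outcome behind
a published cutoff is unstated — and `dichotomize_and_compare` composes
cutoff → KM → log-rank.

## What the simulators emulate — and what they do not

* `simulate_screen`: negative-binomial counts (gamma–Poisson; default
  dispersion 0.05, typical of deep amplicon sequencing) around
  log-normal baseline abundances (sdlog 1.5, leaving roughly 10–20% of
  shRNAs below 25 CPM so the abundance filter is exercised); essential
  genes' day-4 means are multiplied by $2^{\text{effect}}$ uniformly
  across their shRNAs, suppressors by the reciprocal. Defaults: 5
  shRNAs/gene, 3 replicates per arm (screens of this kind rarely report
  replicate structure; 3 is the minimal design the Welch test supports
  comfortably), library size $10^7$ reads. Because sequencing is
  compositional, scaling 10% of the library down 4-fold inflates every
  other CPM by ~7%; raw day4/day0 CPM ratios therefore converge to
  $2^{\text{effect}}$ *times the total-abundance ratio*, and
  effect-recovery checks compare essential against neutral shRNAs
  (ratio of ratios), which converges to $2^{\text{effect}}$ exactly.
  Not modelled: PCR amplification bias, infection bottlenecks, selection
  dynamics, off-target shRNAs (an option plants one null reagent per
  affected gene).
* `simulate_paired_expression`: 32 tumour/normal pairs by default, with a
  shared per-pair effect (SD 0.5) and measurement noise (SD 0.2); planted
  genes shift by ±`de_log2fc` in tumours. Real microarray data add probe
  effects, batch structure and heavier tails.
* `simulate_ranked_transcriptome`: a 1000-gene, 3-vs-3 experiment with one
  50-gene set shifted by −1 log2 unit and 20 uniform decoy sets.
* `simulate_survival_cohort`: exponential event times, hazard ratio
  applied to marker-above-median patients; censoring is a single
  cohort-wide exponential rate calibrated against the mean hazard, so it
  is non-informative and the expected censored fraction equals
  `censor_rate` exactly under HR = 1.
* `simulate_correlated_pairs`: bivariate normal with exact population
  correlation.

Passing planted-truth tests shows the pipeline recovers effects under its
own generative assumptions; it does not certify performance on real data,
whose noise is not NB/log-normal-clean and whose effects are not uniform
across reagents.

## Numerical choices and problem sizes

All randomness flows through explicit `seed` arguments; generators save
and restore the session RNG state, so outputs are bit-reproducible and
independent of call order. One-sided p-values entering Stouffer's
combination are clamped to $[10^{-300}, 1 - 10^{-16}]$. Metric ties in
GSEA ranking resolve lexicographically by gene symbol. The validation
suite uses deliberately modest problem sizes — 500-gene screens, 1000
null replicates for calibration (99% binomial bands), 10–20 seeds for
recovery medians, 1000 permutations for GSEA — chosen so the full suite
documents the pipeline's statistical behaviour in a few minutes on a
laptop while keeping every acceptance band attainable by a correct
implementation rather than by luck.

## Known limitations

* No MAGeCK-style α-RRA or maximum-likelihood modelling; gene evidence is
  filter-then-Stouffer, faithful to the three-criterion design.
* No moderated (limma-style) variance shrinkage in `paired_de`; with 32
  pairs the unmoderated paired *t* is adequately powered.
* No Cox regression, time-dependent ROC or competing risks.
* No microarray/RNA-seq preprocessing; inputs are assumed normalised,
  log2-scale expression.
* FASTQ quantification is exact substring matching (sense strand by
  default, reverse complement optional); no mismatch tolerance, quality
  trimming or adapter handling.
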