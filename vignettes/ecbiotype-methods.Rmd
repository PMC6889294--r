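---
title: "Methods: molecular biotyping of endometrial cancer with ecbiotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular biotyping of endometrial cancer with ecbiotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecbiotype)
```

## The classification model

Endometrial carcinomas fall into four prognostic biotypes — POLE
(ultramutated), MSI (hypermutated), copy-number low (CNL) and copy-number
high (CNH) — originally defined from multi-omic profiling. `ecbiotype`
implements a surrogate that uses only two routine assays: targeted
sequencing of 13 genes and fragment-analysis MSI testing over 8 short
tandem repeat loci. Classification is a strict hierarchy:

1. a retained mutation in the POLE exonuclease domain assigns POLE,
   regardless of MSI status (MSI co-occurs in a minority of POLE tumors and
   is considered secondary to the ultramutator phenotype);
2. otherwise MSI-H assigns MSI;
3. the remainder is split CNL/CNH by a random-forest classifier over the
   12 non-POLE panel genes, each coded as a presence/absence indicator.

The hierarchy is total: every sample with a profile and an MSI status
receives exactly one group. Samples with indeterminate MSI (too few
evaluable markers) fall through to the copy-number branch with a warning
rather than blocking classification, mirroring clinical fallback.

## Variant filtering

A variant is retained when all three hold:

* depth ≥ 600 reads and variant allele fraction ≥ 5%. Both bounds are
  closed: "minimum coverage of 600×" is read as depth 600 passing. The
  thresholds reflect the high-coverage amplicon assay the panel was
  designed for and are configurable via `filter_policy()`.
* Its pathogenicity triage is *retain*: ClinVar pathogenic / likely
  pathogenic / VUS are kept, benign / likely benign discarded, and ClinVar
  takes precedence over in-silico predictors when both are present. For
  ClinVar-unreported variants, a damaging PolyPhen call or a deleterious
  SIFT call retains the variant. When both predictors are uninformative, a
  protein-altering consequence (missense, nonsense, frameshift, inframe,
  splicing) is kept as a VUS and synonymous/intronic/regulatory changes are
  dropped. The retain-if-either-predictor-damaging rule and the
  consequence-based fallback are documented design choices: the source
  protocol excludes only (likely) benign calls and keeps VUS, so a concrete
  tie-break was needed for conflicting or absent predictions.

Rejection reasons (low depth, low VAF, pathogenicity) are counted in a
structured log attached to the filtered table, so samples filtered to zero
remain distinguishable from samples with no data. Filtering is idempotent
and monotone in both thresholds; dichotomization is invariant to row order
and duplicated records. Multi-allelic VCF rows are split into one record
per ALT allele with positional VAFs — lossless for gene-level
dichotomization. Gene assignment is always taken from the annotation
column, never recomputed from coordinates.

## MSI calling

The laboratory practice this replaces is expert visual reading of
electropherograms. As a deterministic surrogate, a marker is called
*unstable* when the tumor trace contains a dominant allele — a peak at
least `rel_peak_frac` (default 0.2) of the tallest tumor peak — whose
fragment length differs from every dominant normal allele by more than
`shift_tol` (default 2 bp, accommodating ±1 bp stutter). A marker is
*failed* when either trace carries total signal below `min_signal`
(default 100 units). These three knobs live in `msi_params()`.

Sample status is MSI-H when at least 30% of evaluable markers are unstable
— with all 8 markers evaluable, 3 or more (2/8 = 25% falls short). Failed
markers shrink the denominator, and fewer than `min_evaluable = 5`
evaluable markers gives *indeterminate* rather than MSS: calling stability
from missing data would bias toward MSS. The cutoff of 5 is a design
choice. Labs that export only per-marker calls can enter the pipeline at
`call_msi_status()` directly.

## The POLE rule

The exonuclease (proofreading) domain bounds default to protein residues
268–471, the standard literature convention; the source protocol never
states bounds, so they are configurable in `pole_rule()`. The branch
requires a *domain* mutation, not any POLE mutation; hotspots p.P286R and
p.V411L are flagged separately. Residues are parsed from HGVS-p strings;
unparseable annotations are excluded from the domain test and counted in a
message rather than failing the run.

## The CNL/CNH random forest

The training resource is a labeled 12-gene binary matrix of 148
copy-number cases (about 40% CNH). The protocol:

* stratified split into 62 training and 86 validation samples
  (largest-remainder apportionment keeps label proportions within one
  sample per class);
* mtry (candidate features per split) tuned over the full grid 1–12 by
  stratified 5-fold cross-validated accuracy, ties broken toward the
  smaller value. The source describes both an "internally split in three
  sets" scheme and 5-fold cross-validation; the latter is more specific
  and is what is implemented (the grid and the accuracy criterion are
  design choices, as the original optimization criterion is unstated);
* 1000 trees, uniform bootstrap, no class weighting; prediction by
  majority vote with the vote fraction exposed.

Everything is reproducible from `(data, seed, mtry, n_trees)`. Variable
importance is the mean decrease in Gini impurity; a feature never chosen
in any split scores exactly 0.

The performance suite (`performance_metrics()`) reports the full binary
confusion-matrix panel. Two deliberate numerical choices: the accuracy CI
is the exact Clopper–Pearson binomial interval, and McNemar's test is the
exact two-sided binomial on the discordant pair counts (capped at 1) —
the exact form is required to reproduce a p-value of exactly 1 under
balanced discordance, where the corrected asymptotic test does not.

## Cohort statistics

* Chi-square association tests use the uncorrected Pearson statistic by
  default; Yates' correction is available by flag. The uncorrected form
  recomputes the published TP53-by-histology table to p ≈ 0.020 against a
  printed 0.021; some other printed univariate p-values do not reproduce
  to printed precision under any standard correction, so only robust
  bounds (p < 0.001) are asserted in tests.
* Rank tests: Wilcoxon rank-sum for two groups (exact for small untied
  samples, tie-corrected normal approximation otherwise) and
  Kruskal–Wallis for more.
* Kaplan–Meier uses the product-limit estimator with censored-at-t
  subjects handled after events at t. The median survival convention —
  earliest time with S(t) ≤ 0.5 — is a documented choice, as the
  convention behind the published medians is unstated.
* The log-rank test uses hypergeometric expectations at each event time,
  df = groups − 1; an all-censored input returns statistic 0 and p = 1
  with a warning instead of an error.

## What the synthetic generator emulates

`simulate_cohort()` and `simulate_training_set()` emulate the study
conditions: group proportions 16/12/48/20 of 96; group-specific Bernoulli
gene-mutation frequencies; per-sample raw mutational loads from a
discretized log-normal (σ~log~ = 0.45) matched to each group's median and
clipped to its observed range (medians 94/40/37/32 for POLE/MSI/CNL/CNH);
every mutated gene realized as at least one filter-passing variant row
plus sub-threshold filler rows; MSI-group samples (and 3/16 of POLE
samples) forced to ≥ 3 unstable markers; 5/16 of POLE domain mutations at
a hotspot; survival with the published group medians (DFS
55.40/38.33/34.43/27.70 months) and 15% censoring.

Frequencies the source never states are free parameters fixed once at
TCGA-typical endometrial values. The most consequential is CTNNB1's
CNL/CNH pair, set to 0.30/0.05: reported CTNNB1 frequencies in
endometrioid EC span roughly 15–50% across cohorts, and the published
importance table places CTNNB1 a distant third (about 28% of TP53's Gini
contribution), so a moderate contrast is the value consistent with the
dataset being emulated; a frequency at the top of the literature range
would make CTNNB1 the dominant discriminator, contradicting the measured
ordering.

Survival calibration: with plain exponential times at the published group
medians, a four-group log-rank at n = 96 has little power, so medians
alone cannot carry the published prognostic separation. The generator
therefore uses Weibull times with shape 2 (increasing hazard, a standard
shape for cancer progression endpoints), parameterised by the group
median; shape 1 recovers the exponential special case and is what the
type-I-error simulations use. This dispersion choice was made once, as the
calibration needed for the simulated cohorts to express the published
significance, and is exposed as `survival_shape`.

What the generator does *not* emulate: gene–gene correlation (draws are
independent Bernoulli given the group), real allele sequences or
coordinates (variant rows carry synthetic positions anchored near each
gene), inter-marker differences in MSI behavior, covariate–survival
confounding, and the case-selection process behind the 148-sample TCGA
matrix. Passing tests on synthetic cohorts therefore validate the
pipeline's logic and the protocol's behavior under the stated marginal
conditions, not performance on real tumors — in particular, importance
rankings among near-equally informative genes are less stable under
independence than in correlated real data.

## The deterministic reference fixture

`build_reference_fixture()` constructs a 96-sample cohort reproducing the
published marginals exactly: truth groups 16/12/48/20; MSI-H in 15 samples
(3 inside POLE); per-gene totals (PTEN 53, ARID1A 47, ARID5B 42, RPL22 41,
TP53 32, CTCF 26, POLE 16, KRAS 9); the stated group-conditional counts;
retained-load median 9.5 (range 2–64); raw-load median 40 (range 13–171)
with the group medians above; 5 hotspot cases; covariate margins
(endometrioid 83 / serous 13, early 79 / advanced 17, grades 45/28/23).
Gene positives are placed by a greedy degree-realization: each gene's
carriers are the samples with the most remaining retained-variant
capacity, which guarantees every sample's mutation count fits its
retained-variant budget; a repair pass ensures every sample anchors at
least one filter-passing row.

The published gene-by-covariate cross-tables are jointly over-constrained
with the other marginals, so the fixture satisfies the marginals and the
histology/stage structure of the PTEN, TP53, RPL22 and POLE tables, and
records everything in a manifest whose constraints are verified by
`check_fixture()` — an independent recount that re-runs the pipeline on
the emitted tables rather than trusting the builder. Exact-class
violations abort the build; best-effort constraints are reported.

Fixture survival times are deterministic within-group quantile spreads
hitting each group's published median, minimum and maximum exactly.
Because those printed ranges overlap heavily, the fixture's log-rank test
is not significant — reproducing the published *significance* is the job
of the calibrated stochastic generator, not of the deterministic
marginal-matching fixture.

## Problem sizes and numerical tolerances in the tests

The suite checks marginal convergence at n = 2000 (tolerance 0.03,
conditioning on realized groups so the check targets the Bernoulli
mechanism rather than group-draw noise), forest generalization over 20
seeded 148-sample cohorts, log-rank size over 200 null simulations and
power over 50 seeded cohorts at n = 96 — sizes chosen to keep Monte-Carlo
error well inside the asserted bands while the full suite runs in a few
minutes. Statistical wrappers are compared to hand-written oracles
(brute-force Pearson sums, rank enumeration, direct O−E log-rank
summation, hand product-limit values) at 1e-9–1e-12.

## Known limitations

* The CNL/CNH surrogate consumes binary mutation indicators only; no
  copy-number data, and no clinicopathological-feature model variant.
* Multivariate survival modeling (Cox regression) is out of scope; the
  survival layer is descriptive (KM) and comparative (log-rank).
* MSI calling assumes summarized peak histograms; raw capillary trace
  files are not parsed.
* Annotations (ClinVar, PolyPhen, SIFT) are consumed as given, never
  recomputed; upstream alignment and variant calling are out of scope.
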