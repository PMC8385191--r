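---
title: "Cross-platform PAM50 subtyping: models, parameters and design notes"
author: "PAM50concord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform PAM50 subtyping: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PAM50concord)
```

# The problem

Breast cancer intrinsic subtypes (basal-like, HER2-enriched, luminal A,
luminal B, normal breast-like) are assigned by correlating a tumor's
expression profile over a fixed 50-gene panel with five subtype
prototype vectors (centroids) and taking the nearest one — single-sample
prediction (SSP).  The same tumor profiled on two platforms (digital
RNA counting vs oligonucleotide microarray) does not always receive the
same label: systematic platform effects distort the measured profile and
therefore the centroid correlations.  This package implements the full
chain needed to study that question — platform-specific preprocessing,
distance-weighted discrimination (DWD) bias adjustment, the SSP
classifier, agreement statistics, survival stratification — together
with a synthetic paired-cohort generator so every stage is testable with
no external data.

# The classifier

For a sample with centered log2 expression $x$ over the gene panel and
centroids $c_1, \dots, c_K$, the call is

$$\hat k = \arg\max_k \rho_S(x, c_k),$$

where $\rho_S$ is Spearman's rank correlation (Pearson correlation of
average-tie ranks) over the genes shared between the sample and the
centroid table.  When $\max_k \rho_S < 0.1$ (strict inequality on the
maximum) the sample is labelled `UNCLASSIFIED`.  Two modes are exposed:
**SSP5** uses all five centroids; **SSP2** drops the normal breast-like
centroid, the convention for tumor-only analyses.  Because Spearman
correlation is invariant to strictly increasing per-sample transforms,
calls are insensitive to per-sample monotone distortions — one reason
rank correlation is preferred across platforms.

Exact correlation ties are broken by the canonical subtype order
(Basal-like, HER2-enriched, LuminalA, LuminalB, Normal-like), with a
warning; ties are measure-zero on real data but the behaviour must be
deterministic.  A correlation that is undefined (a rank-constant
vector) is treated as $-\infty$ in the argmax, so it can never win.

Key parameters (`classifySample`, `classifyCohort`):

* `threshold = 0.1` — the unclassified cutoff on the maximum rho.
* `minGenes = 40` — the minimum gene overlap (of the 50-gene panel)
  tolerated before a sample is refused.  The source convention does not
  state a dropout tolerance; 40/50 refuses samples missing more than a
  fifth of the panel while tolerating routine dropout.  Samples failing
  it are skipped with a warning at cohort level, a hard error at sample
  level.

# Preprocessing

**Digital counts** (nCounter-style): per sample, the mean of the
negative-control rows is subtracted from every probe count (optionally
mean + 2 SD, `backgroundSubtract`), values are clamped at a floor
(default 1 count) so logs stay finite, every count is divided by the
geometric mean of six housekeeper genes (ACTB, G6PD, RPLP0, TBP, TFRC,
UBB) and the ratio is log2-transformed (`housekeepingNormalize`).  The
division happens on the count scale and the log is taken afterwards; the
two orders differ only by a per-sample constant, which gene centering
would remove anyway, but the count-scale division is the documented
contract.  Housekeeper rows are retained (they become near-constant)
so downstream gene matching is unaffected; they are never part of the
classifier panel.

**Microarray**: probe(set)-level log2 values are collapsed to one row
per gene by keeping the probe with the largest interquartile range
across samples (`collapseProbes`).  The IQR is the standard
variability filter for this step; quartiles use the default
linear-interpolation convention (type 7), and IQR ties are broken by
probe row order.  RMA summarization itself is out of scope — the
pipeline consumes already-summarized log2 values.

**Both platforms** are then gene-centered (`centerGenes`): each gene's
within-platform mean (default) or median is subtracted.  Mean centering
is the default because it is the stated convention of the emulated
workflow; the median switch is provided because part of the nearest-
centroid literature median-centers.  Centering is performed
independently per platform, which makes calls sensitive to cohort
subtype composition — a known property of this classifier family, not a
defect of the implementation.

# Centroid completion (KNN imputation)

Incomplete centroid/prototype tables are completed gene-wise
(`imputeMissingKnn`) in the Troyanskaya style: for a missing cell
$(g, c)$, the $k = 10$ rows nearest to $g$ — Euclidean distance over
co-observed columns, scaled by the number of shared columns so rows
with different missingness are comparable — among rows observed at $c$
contribute an inverse-distance-weighted mean.  Distance ties are broken
by row order; zero-distance neighbours (exact duplicates over the
shared columns) take over with an unweighted mean.  Imputed values are
convex combinations of neighbour values, imputation commutes with row
permutation, and a complete matrix passes through untouched — all
asserted as properties in the test suite.

# DWD batch adjustment

Systematic bias between a reference batch and a new batch is removed
along the distance-weighted discrimination direction.  DWD solves

$$\min_{\|w\|_2 \le 1,\, b,\, \xi \ge 0} \sum_i \frac{1}{r_i} + C \sum_i \xi_i,
\qquad r_i = y_i (w \cdot x_i + b) + \xi_i > 0,$$

with $y = +1$ for the reference batch and $-1$ for the new one.
Eliminating the slacks yields the equivalent smooth convex loss
$V(u) = 1/u$ for $u \ge 1/\sqrt{C}$ and $V(u) = 2\sqrt{C} - Cu$
otherwise, which `fitDWD` minimizes over the unit ball by accelerated
projected gradient with a Lipschitz step ($V'' \le 2C^{3/2}$ times the
top squared singular value of the augmented data matrix), adaptive
restarts, and a relative-objective stopping rule.  The tests pin the
achieved objective against an independent general-purpose quasi-Newton
solver on a sphere parameterization of the direction; any solver
reaching the optimum within tolerance is acceptable, and this one does
to well below 1e-5 on small instances.

Numerical and design choices:

* **Standardized DWD**: genes are scaled to unit pooled standard
  deviation before solving; zero-variance genes are excluded and get
  direction weight 0.
* **Direction mapping**: the reported direction is the original-space
  image of the standardized-space direction (elementwise product with
  the per-gene scales, renormalized).  This is the axis along which the
  standardize–fit–adjust–back-transform workflow actually moves samples;
  the hyperplane normal ($w$ divided by the scales) is a different
  vector that, for shifts concentrated on high-variance genes, points
  far from the bias axis.
* **Penalty auto-rule**: $C = 100 / \tilde d^2$ with $\tilde d$ the
  median inter-batch pairwise distance on standardized data — the
  standard heuristic.  Configurable.
* **Center at the first mean** (`adjustBatches`): every new-batch
  sample $x$ becomes $x - ((\mu_{new} - \mu_{ref}) \cdot w)\, w$, which
  equalizes the batch-mean projections on $w$ exactly while leaving
  all orthogonal components bit-unchanged; the reference batch is
  returned untouched.
* **Idempotence caveat**: re-applying the adjustment with the *same*
  model is exactly a no-op (the mean gap along $w$ is already zero).
  Re-*fitting* on adjusted finite data finds the sampling-noise
  component of the mean difference orthogonal to the first direction,
  so a refit-and-readjust moves samples by a small but nonzero amount
  (a few percent of the original shift in the test construction).
  Exact refit-idempotence holds only in the no-noise limit; the test
  suite asserts the exact same-model no-op and bounds the refit
  residual instead.

`pcDiagnostics` returns every pooled sample's coordinates on the first
three principal components of the gene-centered pooled data plus its
projection on the DWD direction — the standard before/after view of a
batch adjustment.

# Agreement statistics

`confusionMatrix` tallies paired calls with the reference platform in
columns; pairs where either platform said `UNCLASSIFIED` are excluded
from the body but counted, so "n pairs total = body + excluded" always
holds.  Per-class accuracy is the diagonal cell over the reference
column total (classified pairs only); overall agreement is the diagonal
proportion of the body — when one pair of a 64-pair cohort is
unclassified, the denominator is the 63-pair body.  Cohen's kappa is
the standard unweighted statistic
$\kappa = (p_o - p_e)/(1 - p_e)$ on the body.  Weighted variants are
deliberately not provided: subtypes are nominal.  On the bundled
paired-call table the unweighted formula gives 0.506; published
summaries of the same table have quoted a larger value (0.60) from an
unstated variant, which this package does not reproduce and does not
assert — the formula value is the tested one.

`ihcCrosstab` tabulates calls against clinical HR/HER2 phenotypes with
an explicit `missing` row; derived per-subtype fractions use only
non-missing records.  `normalPairSummary` reports how many matched
normal tissues are called Normal-like under SSP5 and, among the
remainder, how many share the matched tumor's label.

# Survival

`kmEstimate` and `logrankTest` wrap the survival package's
product-limit estimator and k-group score test behind the module's
contracts (tidy per-group curves anchored at $S(0) = 1$, chi-square
with $k-1$ df, upper-tail p).  Censored subjects tied with an event
time remain at risk for the events at that time (standard convention).
Overall survival uses death from any cause; a breast-cancer-specific
composite event is carried in the clinical records and analyzed on
request.  Survival stratification is run on SSP2 calls, matching the
tumor-only convention.  The test suite checks the estimator against a
hand-rolled product-limit oracle, verifies the null rejection rate of
the log-rank test over 1,000 seeded replicates of 200 subjects, and
pins a small-sample p-value against a 10,000-permutation reference.

# The synthetic cohort generator

`generateCohort` emulates the paired-platform study design this package
targets.  Defaults are the emulated study's conditions and are not
tuning knobs:

* tumor composition Basal-like 23, HER2-enriched 28, LuminalA 55,
  LuminalB 37 (the digital-count cohort's composition), plus 24 matched
  normal tissues;
* 50 classifier genes; centroid entries iid Gaussian with SD
  `separation = 1` log2 units, redrawn until all pairwise centroid
  Spearman correlations are below 0.3 so subtypes are genuinely
  rank-distinguishable;
* platform A sample = its subtype centroid + iid $N(0, 0.5^2)$ log2
  noise; platform B = $a_g \cdot A + b_g$ + independent noise, with
  per-gene scale $a_g \sim U(0.8, 1.2)$ and shift
  $b_g \sim N(0, 0.5^2)$ — the simplest affine structure that breaks
  cross-platform centroid correlation the way systematic platform
  effects do;
* exponential survival with per-subtype hazards (0.095, 0.070, 0.013,
  0.042 per year for basal-like / HER2-enriched / luminal A / luminal
  B) and uniform censoring on [0, 11.6] years, calibrated once so the
  expected censoring fractions are roughly 61/68/93/78 percent — the
  risk ordering of the emulated study;
* IHC phenotypes drawn from a subtype-to-phenotype probability table
  that loosely mirrors the emulated cohort's composition (basal-like
  mostly HR−, HER2-enriched mostly clinically HER2+, luminals mostly
  HR+/HER2−), including an explicit missing-IHC probability.

`expandToProbes` exercises the probe-collapse step: each gene emits
several probe rows, one designated probe per gene drawing its noise SD
from a high range (1.2–1.8) and the others from a low range
(0.05–0.3).  The separated ranges make the intended probe identifiable
by the IQR rule with margin — with a single shared range two probes can
have nearly equal SDs and finite-sample IQR estimates misrank them.
`emulateCounts` turns log2 abundances into raw digital counts with
negative-control rows, housekeeper rows and a per-sample content
factor; in expectation mode the preprocessing chain inverts it exactly
(up to per-gene constants), in Poisson mode it adds realistic counting
noise.

Everything is driven by integer seeds through a save/restore wrapper,
so the same seed yields a bit-identical cohort and generation never
disturbs the caller's RNG stream.

What the generator does **not** emulate: probe-sequence affinity
effects, non-linear cross-platform relationships, FFPE degradation,
tumor-content heterogeneity, or correlated gene-gene noise.  Passing
tests on synthetic cohorts therefore demonstrate the pipeline's
correctness and its behaviour under controlled affine platform bias —
not that any real pair of platforms will reach a particular agreement
level.

# Problem sizes used by the test suite

The suites run at deliberately modest sizes chosen to make the
statistical assertions stable: cross-platform property tests use
cohorts of 60–240 samples over 50 genes; the DWD recovery test uses
120 samples per batch; the log-rank calibration uses 1,000 null
replicates of 200 subjects and a 10,000-permutation reference on 40
subjects; the kappa-vs-shift trend uses a 3-point distortion grid with
20 replicates.

# Known limitations

* Two-batch DWD only; multi-batch harmonization is out of scope.
* No risk-of-recurrence (ROR) or proliferation scoring; no claudin-low
  or other non-PAM50 schemes.
* The kappa variant behind the published 0.60 on the bundled table is
  unknown; only the standard unweighted statistic is implemented.
* Cohort-dependent published quantities (raw-data normal-like rates,
  the survival-curve p-value, censoring percentages) require the
  original cohort's measurements and are outside the machine-checked
  surface; the property suites substitute for them.
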