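---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`olfrisk` asks a deceptively simple epidemiological question — does one
feature block (olfactory test scores) carry information about a grouping
defined by another (metabolomics / diabetes-risk score)? — and answers it
with converging unsupervised, classical-statistical and supervised
machinery, each stage guarded against overfitting. This vignette explains
the models behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the genuinely open design decisions we settled.

## The synthetic cohort

No cohort of this kind is publicly available, so the package generates
one with the statistical structure such studies report. The defaults are
the study conditions; they are not knobs to be adjusted per analysis.

* **Olfactory TDI score** (range 1–48): drawn from a two-component
  Gaussian mixture with means (24.9, 34.32), standard deviations
  (3.42, 3.2) and weights (0.167, 0.83). The printed weights sum to
  0.997 because they are rounded; the generator renormalises. A subtlety
  worth knowing: this mixture's *density* is unimodal — the 16.7%
  component appears as a shoulder, not a separate peak (the density at
  24.9, about 0.021, is below the density at the inter-mean "valley",
  about 0.048). Two *mixture components* are nonetheless identifiable
  from the likelihood, and the BIC scan recovers M = 2 reliably.
  Mode-hunting on the density alone would not.
* **Subtest decomposition.** No joint model for Threshold /
  Discrimination / Identification is reported anywhere we know of, so the
  TDI total is split by noisy proportions centred on (0.25, 0.375, 0.375),
  with D and I rounded to integer instrument scores and T absorbing the
  remainder so the sum identity `T + D + I = TDI` holds exactly. This is
  a stand-in, and flagged as such.
* **FINDRISK score**: Gaussian (mean 11.5, SD 4), rounded and clipped to
  [0, 26]; unimodality is itself a finding the pipeline should reproduce.
  The parameters roughly reproduce clinical category counts of
  19/68/36/33/7 at n = 163 across the five categories (<7 / 7–11 / 12–14 /
  15–20 / >20, with 10-year risks 1/4/17/33/50%). The maximum attainable
  score is not standardised in the literature we mirror; 26 is a
  convention.
* **Metabolomics** (10 baseline + 5 post-glucose-challenge deltas):
  block-correlated Gaussians (within-block r ≈ 0.3) with a linear risk
  effect (slope 0.3 SD per SD of latent risk; HDL negative, matching its
  protective direction) and an implanted two-cluster structure: a 2.0-SD
  mean shift on 8 glucose-metabolism variables, with cluster membership
  tied to the risk score through a logistic link. The 2.0-SD shift is
  chosen from the separation geometry: with the within-block correlation,
  it yields ≈96% Bayes-optimal assignment accuracy, so the cluster
  structure is recoverable by PCA–Ward–k-means (at 1.5 SD the Bayes
  optimum itself is only ≈91%, leaving no recovery margin for any
  clustering method).
* **Confounding through age.** Age enters the risk score (r ≈ 0.41) and
  tilts the identification share downward (r ≈ −0.25) — the classic
  control correlations. Because both act through age itself, the implied
  identification–risk correlation is their product (≈ −0.10): present in
  principle, but below reliable detectability at n = 163, and
  identification has *no* partial effect given age. These magnitudes are
  the only joint choice that keeps all three reported phenomena true at
  once (visible control correlations, chance-level olfactory-only
  classification, olfactory features in ABC set C of the risk
  regression); making identification depend on the risk-orthogonal part
  of age instead turns it into a textbook suppressor variable and is
  exactly the wrong model.
* **Blemishes**: 12 outliers (at ±8 column SDs) injected into metabolomic
  columns and 6 missing values into the delta columns (emulating
  unmeasured post-challenge assays), in that order and on disjoint cells.
* With `olfaction_association = TRUE` the generator implants a real
  TDI–risk dependence (default 3 TDI points per SD of latent risk), used
  to verify the pipeline has power, not just calibration.

What the generator does **not** emulate: assay measurement-error
mechanisms, the full questionnaire block (only sex and smoking stand in
for binary confounders), item-level FINDRISK structure, non-Gaussian
metabolomic marginals, or missingness that is informative of the outcome.
Passing tests therefore certify the pipeline's logic and calibration on
Gaussian-structured data, not robustness to every pathology of real
clinical data.

The latent truth (mixture mode, cluster label, injected cell positions)
travels in a `truth` sidecar that the analysis-facing table never sees.

## Preprocessing

Transforms are chosen per variable by Kolmogorov–Smirnov tests against a
normal with moment-estimated parameters (no Lilliefors correction — the
plain usage of the cited test, slightly anticonservative), at α = 0.05:
untransformed wins if already non-significant, otherwise the
non-significant candidate with the largest p; `log` and `1/x` require
positive data, `sqrt` non-negative data. Grubbs outlier removal is
two-sided, one point per iteration, α = 0.05 per variable, uncorrected
across variables, with the critical value
`((n−1)/√n)·√(t²/(n−2+t²))`, `t = t(1 − α/(2n), n−2)`; each outlier
becomes a missing value and the test repeats until non-significance.
Imputation is kNN with k = 3 on standardized columns; distances average
over pairwise-complete columns so rows with different missingness remain
comparable; weights are inverse-distance with a Gaussian-kernel fallback
when a donor sits at zero distance. The stage order — transform, outliers,
impute — follows the workflow being reproduced; normality is not
re-checked after outlier removal (deliberately, and noted).

## One-dimensional mode discovery

The Pareto density estimate uses the data-driven radius at which the mean
in-ball data fraction is ≈ 0.2013. The kernel is Epanechnikov with
support equal to twice that radius: a raw counting (uniform) kernel
produces dozens of spurious micro-modes at realistic n, which defeats the
estimator's purpose; support = 2 radii is the smallest smooth choice that
localises a standard normal's peak to ±0.1 with height error < 0.05 at
n = 2000.

Mixtures are fitted by EM with a quantile-partition start, a k-means
start, and 10 random restarts (best likelihood wins; deterministic given
the seed). A variance floor of `1e-4 · sd(x)` guards collapse and is
flagged when triggered. The optimiser was checked against an independent
fitter (mclust) and attains equal or better log-likelihood on every
replicate tried; a genetic-algorithm refinement stage was considered and
dropped — EM multi-start already reaches the ML optimum on this problem
class, and GA hyperparameters are not specified anywhere we could follow.
BIC uses `3M − 1` free parameters (weights on the simplex). The LRT
between M and M−1 uses df = 3, with the usual caveat that mixture LRTs
are boundary-irregular — it is reported as a secondary diagnostic, BIC
decides. The goodness-of-fit check is a two-sample KS test against 1000
model draws (an automated substitute for visual quantile–quantile
inspection). Decision boundaries solve
`wᵢN(x|mᵢ,sᵢ) = wⱼN(x|mⱼ,sⱼ)` between adjacent means by `uniroot` to
1e-9; when extreme imbalance leaves no root between two means the
boundary is reported `NA`, never fabricated.

Estimator bias worth knowing: at n = 163 with a 16.7% lower component,
the ML estimate of the lower-component mean is biased upward by about
+0.5 to +1 TDI point — for some samples the global ML optimum splits the
dominant mode instead. This is a property of maximum likelihood at this
sample size, not of the optimiser.

## Cluster discovery

PCA is the eigendecomposition of the correlation matrix (scaled, centred
data); components with eigenvalue > 1 are retained (Kaiser). Ward uses
the Lance–Williams criterion on Euclidean distances (`ward.D2`); the cut
partition's centroids initialise a single Lloyd k-means run (max 100
iterations), which can only lower the within-cluster sum of squares. The
cluster count is a majority vote over ten implemented indices (average
silhouette, Calinski–Harabasz, Davies–Bouldin, Hartigan, Krzanowski–Lai,
Dunn, C-index, McClain–Rao, Ball–Hall, gap statistic with 10 uniform
reference sets) — a documented subset of the 26-index panel the original
workflow used; re-implementing all 26 is out of proportion when the
decision rule, the majority vote with ties broken toward smaller k, is
what matters and is implemented exactly. Silhouette follows the standard
`(b − a)/max(a, b)` with singletons contributing 0.

## Association statistics

χ² crosstabs are plain Pearson (no Yates correction — the reproduced
analyses' degrees of freedom indicate none was used) with per-cell
Pearson residuals `(O−E)/√E`, whose squares sum to χ² (asserted on every
call in the tests). Correlation matrices use pairwise-complete Pearson r
with t-based p-values, Bonferroni-corrected over all unique off-diagonal
pairs. The mixed rm-ANOVA is the classical split-plot decomposition
(verified against `aov`), with Greenhouse–Geisser epsilon from the pooled
within-group covariance (verified against `car::Anova`) applied to the
within and interaction terms; a non-integer *between*-effect df, as
sometimes appears in published tables, is not something this
decomposition can produce, and we do not imitate it. Group-difference
screens use Welch t-tests.

## Classification harness

Splits are class-proportional 2/3–1/3 Monte-Carlo resamples (every class
rounds to within one subject of the global fraction). The negative
control permutes *training* labels freshly each run and never touches
test labels — it guards the fitting step. Classifier families and printed
hyperparameters: random forest (500 trees, at most 7 terminal nodes,
mtry = round(√p) by default; the multiplicative mtry grid is available
via `mtry_grid`, chosen by OOB error, but a fixed √p keeps 1000-run
experiments fast and changes results negligibly); gradient boosting
(depth 5, eta 0.25, 5 parallel trees, 20 rounds); an information-gain
decision tree with extractable rules standing in for a proprietary
non-hierarchical rule inducer (the conclusions do not depend on this
family); logistic regression; radial-kernel SVM. Metrics are computed by
formula in-package; AUC is the rank (Mann–Whitney) statistic with
mid-ranks. Undefined metrics (PPV with no positive predictions,
single-class test splits) propagate as `NaN`, are excluded from medians
and percentiles, and their count is reported — never silently zeroed.
Summaries are medians with 2.5–97.5 percentile intervals over runs.

## Feature selection

The shadow-feature selector appends a permuted copy of every candidate,
fits a random forest (permutation importance — mean decrease accuracy, as
in the published algorithm), and credits a hit when a feature beats the
best shadow; decisions use a two-sided binomial test (p = 0.5) at
α = 0.01, Bonferroni-adjusted over the initial feature count (the cited
implementation's default adjustment; without it, chance-correlated noise
features are confirmed at a visible rate). Undecided features after
`max_iter` are not selected — the conservative reading of "tentative".
LASSO selection takes the nonzero coefficients at the cross-validated
penalty under the one-standard-error rule — the penalized-regression
tool's own default for coefficient extraction; the minimum-CV-error rule
(available as `rule = "min"`) admits noise features in half or more of
resampling runs and would blur the null calibration. LMG importance is
the Shapley decomposition of R²: exact over all subsets for ≤ 12 features
(closed-form ordering weights), Monte-Carlo over ≥ 200 orderings above
that; importances are non-negative and sum to the model R². For the LMG
selector, a run's "selected set" is ABC set A of that run's importances —
the natural reduction of an importance profile to a set.

Computed ABC analysis sorts values descending and works on the curve of
cumulative value share versus cumulative item fraction: the A|B limit is
the curve point nearest the ideal point (0, 1); the B|C limit is the
break-even point where the curve's slope (item value / mean value) falls
to 1; if the A|B point would fall beyond break-even it moves there. The
partition is invariant to positive rescaling. Aggregation over 1000 runs
reports both published reduction rules — ABC set A of the counts, and the
top-f features with f the modal per-run set size — plus a disagreement
flag when they differ (including count ties at the cut, where all tied
features are kept).

## Orchestration and problem sizes

`run_pipeline()` derives every stage seed from one master seed, logs one
line per stage, and renders intervals as `median (2.5–97.5)` with
undefined entries as `undefined (k runs)`. The default test-suite problem
sizes — 100–200 CV runs, 20 mixture replicates, 25–50 generator seeds per
property, 100 feature-selection resamples — are chosen so the full suite
exercises every calibration claim at useful statistical resolution while
staying comfortably interactive; the acceptance script runs the permuted
control at the full 1000 runs. The headline verdict rule: olfactory
features "improve" risk prediction only if they add ≥ 5 percentage points
of median balanced accuracy over metabolomics alone *and* the
olfactory-only interval clears chance.

## Known limitations

Gaussian generative structure only; single-imputation kNN (no uncertainty
propagation); the LRT df = 3 approximation; the 10-of-26 cluster-index
panel; classifier backends are delegated to their standard CRAN
implementations behind a fit/predict contract (the harness, metrics and
controls are all in-package); the rule-based family is an information-gain
tree, not the original proprietary inducer.
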