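---
title: "Methods and design choices in pairomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in pairomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pairomics` analyses paired before/after-intervention (BT/AT) cohorts with
three molecular blocks per participant: buccal-cell histone PTMs, PBMC
histone PTMs, and plasma protein groups. This vignette documents the
statistical procedures, the parameters that matter, the synthetic-cohort
generator that the test suite relies on, and the decisions taken where the
design was genuinely open.

## Preprocessing

**Stage order** is fixed: filter → quantile normalize → classify
missingness → impute → batch adjust → (PTM blocks) relative abundance.
Imputation runs after normalization so that the censored-tail statistics are
computed on comparable per-sample distributions.

**Filters.** PTM features with 10 or more missing values over the paired
samples are removed. Plasma protein groups must be observed in at least 9
paired participants at BT *and* at least 9 at AT (an AND rule; with 11
plasma pairs this is an 80 % coverage requirement). Both thresholds are
arguments.

**Quantile normalization** maps each sample's observed values onto the
cross-sample mean quantile vector. Ranks ignore missing cells: each
sample's empirical quantile function is interpolated on a common grid of
the block's feature count, the reference is the mean of these functions,
and each observed value is assigned the reference quantile at its own
(fractional, tie-averaged) rank. Complete samples therefore end up with
identical sorted vectors, and the operation is idempotent on complete
matrices — both are asserted in the tests.

**Missingness classification.** Per (feature, condition BT/AT): NMAR when
the missing fraction strictly exceeds 0.75, MAR when some but at most 75 %
are missing, OBSERVED otherwise. Equality at exactly 75 % resolves to MAR;
the boundary is open in the source description and the less drastic
imputation model is the safer default.

**Imputation.** NMAR cells are drawn from N(μ_low, σ_med²) with μ_low the
mean of all observed values below the block-wide 1st percentile and σ_med
the median over features of the per-feature SD (n−1 denominator). MAR cells
are drawn from N(condition mean of the feature, 0.5²), log2 scale. Both the
percentile and the SD pool are computed block-wide over observed values
only: at 12 samples per condition, per-sample versions of these statistics
are too unstable, and the block-wide choice is documented here because the
source description leaves it open. A MAR (feature, condition) without any
observed value falls back to the NMAR rule with a warning (unreachable
under the 75 % rule, kept as a guard).

**Batch adjustment** delegates to `sva::ComBat` (parametric empirical
Bayes, no covariates — none are described for the adjustment step). The
empirical-Bayes shrinkage deliberately leaves per-feature sampling noise in
place; what the adjustment guarantees, and what the tests assert, is that
the *across-features mean* batch difference collapses (≈ 0.03 after a
planted shift of 2) while a planted BT/AT effect orthogonal to batch is
preserved (correlation ≥ 0.999 of effect estimates before/after).

**Relative abundance** converts log2 intensities to the linear scale before
forming percentages within each precursor group
(p_i = 100·2^{x_i}/Σ_j 2^{x_j}); percentages of log-scale values would be
meaningless, so the conversion is explicit. Partially observed groups are
normalized over their observed members; fully missing (group, sample)
combinations stay missing.

## Marker discovery

The composite rule requires, per feature: BH-adjusted paired t-test
q ≤ α, BH-adjusted paired Wilcoxon signed-rank q ≤ α (both two-sided,
α = 0.05, AND), and a jackknife 95 % lower confidence bound of the PLS-DA
VIP score of at least 1. Benjamini–Hochberg is used for the multiple-testing
correction throughout, for consistency with its explicit use in the
health-awareness stage.

**Wilcoxon exact null.** Cohorts of 11–12 pairs make the normal
approximation poor, and constant shifts produce fully tied absolute
differences for which the classical exact distribution is undefined. The
signed-rank p-value is therefore computed by complete enumeration of the
2^n sign patterns for n ≤ 14 (exact even under ties; for 12 pairs with a
constant positive shift this gives p = 2·(1/2)^12 ≈ 4.9·10⁻⁴), by
`psignrank` for larger untied samples, and by the tie-corrected normal
approximation otherwise. Zero differences are dropped; a feature whose
differences are all zero reports p = 1 for both tests.

**PLS-DA** is fitted by NIPALS on autoscaled features with the class coded
as a centered indicator matrix; two components by default. The model is fit
on sample profiles with class BT/AT (matching sample-level class
separation maps), while effect sizes use the paired changes — the
alternative of fitting on difference vectors was considered and not
adopted. VIP aggregates both components,
VIP_j = √(p·Σ_a SS_a w²_ja / Σ_a SS_a) with SS_a = (tᵃ'tᵃ)(qᵃ'qᵃ), so that
Σ_j VIP²_j = p holds identically (asserted to 1e-8 on every fitted model).
Zero-variance features are excluded with a warning.

**Jackknife.** Leave-one-participant-out (both samples of the participant
removed), delete-1 SE from the replicate spread
(SE² = (n−1)/n · Σ(θ₍₋ᵢ₎ − θ̄)²), and a t quantile:
CI = VIP_full ± t_{n−1,0.975}·SE. The CI construction is not specified in
the source; the delete-1/t construction is used consistently here and in
the healthy ranges.

**Effect sizes** are means over complete pairs of AT − BT: log2 fold
changes for plasma intensities, percentage-point differences for PTM
relative abundances.

**Power conventions.** The selector's planted-power property (sensitivity
≥ 0.8, FDR ≤ 0.1 with 20 planted markers out of 200 at 12 pairs) is
evaluated at a planted effect of 1.5 × the SD of the *paired difference* —
the noise scale a paired analysis works against. Measured against the
per-measurement SD the same configuration has roughly half that power;
this is a property of paired designs at n = 12, not of the implementation.

## Integration

**Affinities.** Participant change vectors (AT − BT, restricted to the
discovered markers; a full-profile switch exists) enter the
similarity-network-fusion kernel: squared Euclidean distances, local
bandwidth ε_ij = (ε_i + ε_j + d²_ij)/3 with ε_i the mean squared distance
to the K nearest neighbours, W_ij = exp(−d²_ij / (2 μ ε_ij)). Defaults
K = max(2, ⌊n/3⌋), μ = 0.5, t = 20 iterations — standard settings; the
source states none.

**Fusion** cross-diffuses each view's full transition matrix through the
other views' KNN-local kernels, symmetrizing and renormalizing each
iteration, and averages the views at the end. The fused diagonal is then
set to the median of the whole matrix, the convention used for display and
clustering of the fused participant network.

**Spectral clustering** uses the normalized Laplacian with row-normalized
leading eigenvectors and seeded k-means (25 restarts); `k = "auto"` picks
the largest eigengap in [2, n/2]. A disconnected affinity graph returns its
components with a warning.

**Cross-omics network.** Pearson correlations between every (PTM change,
protein change) pair over shared participants; edges where |r| ≥ 0.7,
signed. This direct change-correlation procedure deliberately replaces a
multi-block latent-variable (sparse generalized CCA) analysis: the
correlation threshold is defined on raw change correlations, which makes
the edge semantics transparent and testable (threshold boundary, sign, and
positive-scaling invariance are all asserted). Full multi-block GCCA
estimation is out of scope.

**Dendrogram comparison** uses average-linkage hierarchical clustering on
Euclidean distances per block and reports the Pearson correlation of the
cophenetic-distance vectors; the linkage is not named by the source, and
average linkage is the default of the comparison tools in this area.

## Response classes

**Baseline adjustment.** Raw agility percent change 100·(AT−BT)/BT per
metric is regressed on the BT baseline; the adjusted value is the residual
re-centered at the cohort mean change. With no baseline variation the raw
change is returned. At n = 12 the fitted-slope noise propagates a few
percentage points into the adjusted values — visible in the synthetic
cohorts as occasional merging of the two lower performance categories.

**GMM categories.** Diagonal-covariance Gaussian mixtures (`mclust`,
model "VVI") with k = 1..4 selected by BIC, under a conjugate regularizing
prior (`mclust::priorControl()`). The prior matters: without it, 12-point
cohorts intermittently produce degenerate two-point components with
collapsed variances and BIC then overfits k. With it, three planted groups
at mean changes 5/25/60 (SD 2) are recovered exactly (k = 3, ARI = 1, 25/25
seeds). Components are ordered by mean overall change to yield the ordinal
labels moderate < intermediate < max.

**Trend classification** replaces shape clustering with a deterministic
rule at tolerance tol = 0.25 of the profile range: a monotone profile with
step difference within tol·range is linear; |m1−m2| ≤ tol·range with
|m3−m2| > tol·range is a first-two plateau (symmetrically for last-two);
anything else, including flat profiles, is none. "Unimpaired" participants
are excluded from self-assessment profiles before averaging.

## Health awareness

Per sample type × lifestyle component (exercise / diet / BMI; healthy
categories sportive / balanced / normal), a 2-component PLS-DA map is
fitted on BT profiles only; AT profiles are projected with the frozen
centering/scaling and rotation (no refitting; the projection is affine,
asserted against a hand-computed linear-algebra oracle).
d_BT−AT is the Euclidean distance between a participant's BT and projected
AT coordinates; it is rotation-invariant in the variate plane. Kendall's W
uses within-rater ranks (mean ranks for ties, larger distance = higher
rank) and the tie-corrected formula with χ² = m(n−1)W, df = n−1.

**Healthy ranges and similarity.** Indicators are map features with
VIP ≥ 1. Values are min–max normalized to [0, 1] against the cohort's AT
values (BT values beyond the AT extremes are clipped). The healthy range is
the delete-1 jackknife mean ± t SE of the healthy members' normalized
values, clipped to [0, 1]. The weighted similarity score uses inclusive
bounds, a linear decay over one range-width r_j = max(hi−lo, 0.05), a floor
at 0, and VIP weights: score = Σ w_j s_j / Σ w_j. This concrete formula is
this package's definition (the original's exact form is not published in
the main text); it is monotone — moving any indicator toward its range
never lowers the score — and equals 1 exactly when every indicator is in
range, both asserted. BT-vs-AT comparisons are one-sided paired t-tests
(AT > BT) with BH correction across the nine (sample × lifestyle) cells;
degenerate constant differences are handled at the limit (all-zero →
p = 0.5, constant positive → p → 0). The d_BT−AT-versus-baseline-distance
relation uses Huber M-estimation (k = 1.345, IRLS to 1e-8) with a Wald
slope test; exact linear data short-circuits to the least-squares line
(the M-scale degenerates there).

## The synthetic cohort generator

The generator emulates the statistical structure of the motivating study
and gives every stage an exact oracle (`TruthTable`): 12 paired
participants for both PTM blocks; a plasma block of 30 samples in three
batches of 8/16/6, including 7 before-only dropout participants and one
completer without an AT sample, so 11 plasma pairs remain; per-block
feature counts 60/60/340 with PTM precursor groups of 2–5 modified forms.

Choices the source does not constrain, fixed once and documented:

* **Intensity model**: per-feature means uniform on log2 [16, 30], Gaussian
  residual noise SD 0.5 — the simplest model consistent with log2-scale
  processing.
* **Planted markers** (10/10/30 per block): BT→AT shift of 1.5 log2 units
  at the intermediate category, scaled per participant by the trend-shape
  multipliers (0.5/1.0/1.5 linear; 0.5/0.5/1.5 and 0.5/1.5/1.5 plateaus),
  alternating sign across markers. The truth table records the
  effect-profile shape after the sign flip.
* **Latent clusters**: with the default 3 clusters, cluster labels coincide
  with the performance categories — the marker-response amplitude is
  category-scaled, so clusters are expressed in the marker changes, the
  situation of a cohort whose fused epigenetic clusters track therapy
  response. An additive per-cluster signature (SD 0.8) on a random third of
  the non-marker features adds cluster structure beyond the markers.
* **Missingness**: left-censoring is abundance-driven — every cell of a
  feature whose mean intensity lies below the block-wide 15 % quantile is
  masked with probability 0.95, plus 2 % random (MCAR) masking. Modelling
  detection dropout at the feature level reflects label-free proteomics
  (low-abundance analytes fail detection wholesale) and makes the
  missingness mechanism identifiable by the 75 % rule; with purely
  cell-level censoring, features partially below the threshold are
  intrinsically mislabelled and no threshold rule can reach high agreement.
* **Batch effects**: additive offsets spread symmetrically with spacing 1.0
  log2 units and multiplicative factors spread around 1.25, each with small
  magnitude-proportional jitter — so zero-magnitude settings degenerate to
  the exact identity.
* **Agility**: baselines uniform on [100, 300] force units; percent changes
  5/25/60 (SD 2) by performance category.
* **Lifestyle**: half the cohort in the healthy category of each component
  (sportive / balanced / normal).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: peptide chemistry and raw spectra, retention
times, correlated feature blocks beyond precursor groups and cluster
signatures, heavy-tailed intensity noise (a config switch exists for the
noise model but the default is Gaussian), non-random dropout of
participants, and questionnaire measurement error. Marker "FDR" measured
against the planted list alone is conservative on default cohorts: the
cluster signatures and the within-group renormalization of relative
abundances create genuinely changed non-planted features.

## Problem sizes and determinism

The test suite and the acceptance script use desk-scale problem sizes
chosen to keep the full run in the low tens of seconds while leaving the
Monte-Carlo margins comfortable: 200 features × 12 pairs with 25–50
repeats for selector calibration and power, 25 seeds for SNF recovery and
trend recovery, 100 seeds for the health-shift power check, and 1000 draws
for imputation moments. All randomness flows from explicit seeds; the
pipeline derives one sub-seed per stage from the master seed (a hash of
the stage name folded into the seed), so skipping or re-running a stage
never shifts another stage's random stream. Identical configs reproduce
identical manifests, including output checksums.

## Known limitations

* Cluster recovery on default synthetic cohorts is intentionally hard
  (amplitude differences of 0.75 log2 units against 0.7 difference noise at
  n = 12); fused-clustering ARI fluctuates around 0.1–0.5 across seeds.
  The dedicated planted-cluster scenario (cluster-mean SD 2.5 against unit
  noise, two complementary views) is where exact recovery is asserted.
* The baseline adjustment propagates slope-estimation noise at n = 12; GMM
  category recovery from agility data is therefore imperfect by design.
* The 75 % missingness rule cannot attribute partially censored features;
  see the generator notes above.
* Wilcoxon exact enumeration is limited to n ≤ 14 pairs (2^n patterns);
  beyond that the exact-untied/normal-approximation fallbacks apply.
* `combat_adjust` requires complete data and ≥ 2 samples per batch; it runs
  after imputation by construction.
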