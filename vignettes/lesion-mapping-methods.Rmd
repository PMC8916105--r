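---
title: "Methods: surface-based lesion mapping, permutation inference and outcome modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-based lesion mapping, permutation inference and outcome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fcdmap)
```

This vignette documents the statistical machinery in `fcdmap`, the
choices made where the methodology was genuinely open, and what the
synthetic-cohort tests do and do not establish about real data.

## Data model

All analyses operate on a template triangle mesh per hemisphere with
unit-sphere registration coordinates. The template is assumed
bilaterally symmetric, so left and right hemispheres share vertex
indices and `pool_to_left()` is a pure re-tag. Vertices are indexed
1..V inside R; files preserve vertex order so 0-based ecosystems line
up row by row. Masks are binary per-vertex indicators, one lesion per
patient. The cohort table carries the clinical schema described in
`?cohort_table`; validation tolerates ±0.51 years of slack between
duration and the scan/onset age difference, so whole-year reporting
does not trip the invariant check.

## Lesion features

- **Closing** (`close_mask`): morphological closing on the 1-ring
  adjacency graph — k dilations then k erosions with the
  self-plus-neighbours structuring element. Default k = 1: this fills
  single-vertex defects, which is the scale of hole that mask
  resampling produces; the iteration count is configurable because no
  canonical value exists. Closing is extensive, monotone and
  idempotent; the test suite verifies all three against a brute-force
  set-based oracle.
- **Lobar categorisation** (`assign_lobe`): majority lobe of the
  lesional vertices. Lesions mostly in the two smallest lobes
  (cingulate, insula) are reassigned to the largest-overlap major lobe
  so lobar statistics are not dominated by tiny parcels; a lesion
  touching only cingulate/insula keeps its lobe. Exact ties break in
  the fixed order frontal, temporal, parietal, occipital — an arbitrary
  but deterministic and documented rule.
- **Eloquent overlap** (`eloquent_overlap`): fraction of the *lesion*
  inside eloquent cortex, in [0, 1]. This convention makes the outcome
  model's overlap coefficient directly interpretable: a coefficient of
  −1.39 at 50% overlap shifts the log-odds by −0.695. The eloquent
  mask is the union of motor (precentral) and visual (pericalcarine,
  lateral occipital, cuneus, lingual) labels bilaterally plus language
  labels (pars opercularis, pars triangularis, transverse temporal) on
  the left hemisphere only.

## Atlas stability and the learning curve

`bootstrap_stability()` draws, per repetition, a reference subset and a
*disjoint* test subset of each requested size, and records the Spearman
correlation between the two frequency maps over all vertices (zeros
included, average ranks for ties). Disjointness prevents a test subset
from being correlated with a reference map that contains its own
patients, which would inflate small-subset correlations; a flag
disables it for the identity sanity check. The reference subset is
redrawn per repetition.

The learning curve `r(n) = r_inf − a·n^(−b)` is the standard
three-parameter inverse power law for performance-versus-sample-size
extrapolation, fitted by Levenberg–Marquardt least squares to the mean
correlation per size. `required_n` inverts the fitted curve at a
stability threshold (default 0.95, configurable — no canonical
definition of "stable" exists); if the fitted asymptote sits below the
threshold the target is reported as unreachable. Degenerate (constant)
input short-circuits to the observed constant.

## Vertexwise permutation inference

At each vertex covered by at least `min_coverage` lesions (default 5,
and at most n − 5, so both outcome classes exist), lesion presence is
regressed on all clinical factors jointly. Continuous predictors are
standardized; binary ones coded 0/1. A small ridge penalty (default
1e-4 on the standardized scale, settable to 0) keeps vertices near
quasi-separation numerically stable; fits that still fail to converge
are flagged and excluded. The per-vertex fits share one design matrix,
so they are evaluated by a batch IRLS kernel in C++; the test suite
cross-checks it against `glm()` at ridge 0.

The null model permutes the covariate *rows as whole rows* against the
masks, preserving the correlation structure among covariates while
severing any link to lesion location. Two inferential levels follow:

1. **Vertex level**: a factor flags a vertex when its observed
   coefficient falls outside the 2.5–97.5 percentile band of that
   vertex's null coefficients. Under the null ~5% of vertices flag by
   chance.
2. **Map level**: a factor is significant when its flagged-vertex count
   exceeds the `100 − 5/n`-th percentile of the per-permutation null
   counts, n being the number of factors tested.

One design choice deserves emphasis: the observed coefficient is
*pooled into* the null distribution before the percentile bands are
computed. Without pooling, each permutation is compared against a band
containing its own value while the observed is not — an asymmetry that
is negligible at 1000 permutations but measurably anti-conservative at
the reduced permutation counts used in tests (family-wise false-positive
rates near 13% instead of ~8% at 60–99 permutations in our null
simulations). With pooling, observed and permuted cohorts are
exchangeable under the null by construction. The same convention is
used for the patient-level outcome permutation test. Residual map-level
inflation at very small permutation counts stems from estimating a 99th
percentile from few draws and disappears as `n_perm` grows toward the
default 1000.

Factors whose definition is intrinsically coupled to vertex coverage —
lesion size above all: larger lesions cover more vertices — show
genuine vertexwise associations even in cohorts with no planted
couplings. Calibration checks therefore test factors that are generated
independently of placement (sex, onset age, duration, MRI-negative
status, hemisphere).

Duration of epilepsy and age at scan are collinear by construction
(scan age = onset age + duration), so they live in mutually exclusive
model variants (`factor_spec(variant = ...)`), mirroring standard
practice for this analysis.

## Spin tests

`spin_correlation_test()` measures the Spearman correlation of two
per-vertex maps and builds the null by resampling *one* map under
random rotations of the registration sphere (uniform over SO(3), QR
with sign correction), nearest-vertex interpolation. Rotating one map
only is the convention of the spin-test literature; the p-value is
two-sided on |r| with add-one smoothing,
`p = (1 + #{|r_null| ≥ |r|}) / (1 + n_rotations)`, so p = 0 is
impossible. Rank-based correlation makes p invariant to monotone
transforms of either map. Analyses run on the left hemisphere after
pooling; no mirrored bi-hemispheric rotation is attempted. The
comparator "cortical axis" map for synthetic work is a deterministic
low-order spherical-harmonic gradient (`axis_map`), standing in for a
published primary-to-association axis, which real analyses would load
as an input map.

## Outcome models

Three patient-level logistic models of seizure freedom (Engel class I,
≥1 year follow-up, operated patients only):

1. **location** — per-vertex logistic regression of seizure freedom on
   lesion presence; a patient's predicted likelihood aggregates as the
   mean fitted probability over their lesional vertices (the
   aggregation rule is our choice; nothing canonical exists for it).
2. **presurgical** — duration (or age at scan), onset age,
   MRI-negative status, scanner field strength (reference 1.5 T),
   eloquent overlap (raw 0–1), lesion size.
3. **with_histology** — adds histopathological subtype and a
   subtype-by-size interaction.

Continuous predictors are Box–Cox-normalized then standardized so
coefficient magnitudes are comparable across predictors; eloquent
overlap stays on its natural scale so the analytic probability
translation (`predicted_probability`) holds exactly. Missing data are
handled complete-case per model: rows are dropped only for the fields
that model uses.

Coefficient significance uses outcome-label permutation with the same
pooled 2.5–97.5 band as the vertexwise procedure. Cross-validation is
stratified k-fold (default 10) with a fixed seed; fold assignment is
anchored on sorted patient identifiers so results do not depend on row
order. Held-out probabilities are dichotomized at 0.5 (the package
reports the threshold; none is canonical) and pooled into one confusion
matrix for sensitivity, specificity, PPV and NPV.

## Pairwise screen

Variable kinds select the test: correlation (Pearson by default,
Spearman by option) for continuous–continuous, Welch t for
continuous–binary, one-way ANOVA with Tukey HSD post hocs for
continuous–categorical, Pearson chi-square (no continuity correction)
otherwise. "Heavily skewed" continuous variables (|skewness| > 1 — the
threshold is our choice) are Box–Cox normalized first, with a +1 shift
when the minimum is ≤ 0. All raw p-values are pooled into a single
Benjamini–Hochberg family at α = .05; applying BH per row is available
by configuration. A post hoc after a chi-square has no canonical
"Tukey" analogue; the package uses Holm-corrected pairwise
two-proportion z-tests and labels them as such. Pairs with fewer than
three complete cases are reported untestable rather than dropped
silently.

## Synthetic cohorts: what they emulate

`simulation_params()` defaults encode a realistic multicentre FCD
cohort: onset age log-normal with median 6 years, duration log-normal
with median 10 years, 1:1 sex ratio, 32% ever-MRI-negative, 18% of
scans at 1.5 T, histopathology available in 66% with subtype mix
11/31/52/6% (I/IIA/IIB/III), 73% operated, follow-up median 2 years.
Lesions are geodesic discs (breadth-first ring growth — graph distance,
not exact geodesics, which is sufficient for the statistics and fast)
with ring radius uniform on 1–4, centred on draws from a smooth
three-bump von Mises–Fisher density. The default coupling tilts lesion
centres of late-onset patients toward the high end of the surrogate
axis (effect 0.8 per SD of onset age); outcomes follow a logistic model
with planted coefficients (eloquent overlap −1.39, 3 T vs 1.5 T +1.04,
−0.35 per SD of log duration, −0.2 per SD of lesion size, MRI-negative
−0.32, intercept 0 — giving ≈65% seizure freedom overall).

What passing tests show: the estimators recover planted parameters, the
permutation and spin procedures are calibrated under their nulls, and
the pipeline is deterministic and self-consistent. What they do not
show: robustness to multi-lesion patients, site effects, registration
error, mask-boundary heterogeneity, or lesion morphologies beyond
discs — none of which the generator emulates.

## Numerical notes and problem sizes

- IRLS: deviance-change convergence at 1e-8, 25 iterations, linear
  predictor clamped at ±30, weights floored at 1e-10; non-converged
  fits are excluded and reported.
- Learning-curve fit: `minpack.lm::nlsLM`, bounds r_inf ≤ 1, a > 0,
  0.001 ≤ b ≤ 5; `required_n` uses a 1e-9 slack before the ceiling to
  absorb representation error at exact thresholds.
- Spearman correlations use average ranks for ties throughout.
- Volume export splats each vertex to its containing voxel under the
  inverse affine, keeping the maximum per voxel; ribbon-filling
  projection is out of scope.
- Tests and the acceptance script run at deliberately modest sizes —
  162/642-vertex icospheres, cohorts of 60–2000, permutation counts of
  60–200, with 10–150 replicate cohorts per calibration claim — chosen
  so the whole suite completes in minutes while Monte Carlo error stays
  well inside the asserted bounds.

## Known limitations

The pipeline assumes vertex-registered masks (no volumetric-to-surface
projection), one lesion per patient and no site-level random effects.
The location-only model's patient-level aggregation is heuristic. The
`required_n` estimate inherits the usual fragility of extrapolating a
fitted learning curve beyond observed sizes. GIFTI I/O is not bundled;
per-vertex maps use a documented plain-text format and volumes NIfTI.
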