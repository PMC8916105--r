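# fcdmap

Surface-based lesion mapping and outcome modelling for focal cortical
dysplasia (FCD) cohorts.

FCD is a malformation of cortical development and a leading cause of
drug-resistant focal epilepsy. When lesion masks from many patients are
registered to a common template cortical surface, three questions become
tractable: *where* do lesions concentrate, *which clinical factors* are
associated with lesion location, and *how does location shape the chance
of seizure freedom after surgery*. `fcdmap` implements the full analysis
chain for such cohorts — and ships a synthetic-cohort generator so every
stage can be developed, tested and demonstrated without clinical data.

## What it computes

Given per-patient binary lesion masks `L_i ∈ {0,1}^V` on a bilaterally
symmetric template mesh with V vertices, a parcellation with lobe
groupings and an eloquent-cortex label set, and a clinical table
(sex, age at onset, duration, MRI-negative status, scanner field
strength, histopathology, surgery and outcome):

- **Lesion atlases** — vertexwise frequency map `c_v = Σ_i L_iv`, the
  likelihood atlas `c_v / max(c)` (peak = 1), subtype-stratified maps,
  a percent-seizure-free map, and NIfTI volume export.
- **Atlas stability** — bootstrap subsampling: frequency maps from
  subsets of size n are rank-correlated with a disjoint reference
  subset's map; a three-parameter learning curve
  `r(n) = r_∞ − a·n^(−b)` is fitted and inverted to estimate the sample
  size needed for a stable atlas.
- **Vertexwise inference** — at every sufficiently covered vertex, a
  multivariate logistic regression of lesion presence on the clinical
  factors (standardized, small configurable ridge). Coefficients are
  tested against permuted cohorts: a vertex is flagged when its observed
  coefficient falls outside the 2.5–97.5 percentile band of the
  permutation null (≈5% of vertices flag by chance), and a factor is
  map-level significant when its flagged-vertex count exceeds the
  `100 − 5/n`-th percentile of the null counts (n factors tested).
- **Spin tests** — correlations between two cortical maps are tested
  against nulls built by random spherical rotations of one map, which
  preserve spatial autocorrelation;
  `p_spin = (1 + #{|r_null| ≥ |r|}) / (1 + n_rotations)`.
- **Outcome models** — logistic models of postsurgical seizure freedom:
  location-only (vertexwise), presurgical factors (duration, onset age,
  MRI-negative status, scanner, eloquent overlap, lesion size), and a
  variant adding histopathology with a size interaction. Significance by
  outcome-label permutation; predictive value by stratified 10-fold
  cross-validation (sensitivity, specificity, PPV, NPV). The
  eloquent-overlap coefficient acts on its natural 0–1 scale, so
  `invlogit(logit(p₀) + β·Δ)` translates it directly into probability
  drops.
- **Pairwise screen** — every pair of cohort variables tested with the
  kind-appropriate test (correlation / t / ANOVA+Tukey / chi-square),
  Box–Cox normalization of heavily skewed variables, and
  Benjamini–Hochberg FDR control at α = .05.
- **Synthetic cohorts** — icosphere template, geodesic Voronoi
  parcellation with eloquent analogues, geodesic-disc lesions drawn from
  a smooth nonuniform density (optionally tilted along a smooth cortical
  axis by planted covariate couplings), and outcomes from a logistic
  model with planted coefficients.

## Worked example

```r
library(fcdmap)

mesh <- make_sphere_mesh(2)                      # 162-vertex template
parc <- make_parcellation(mesh, n_regions = 24, seed = 2)
sim  <- sample_cohort(mesh, parc, simulation_params(n_patients = 200,
                                                    seed = 42))

freq <- frequency_map(pool_to_left(sim$masks))
freq
#> frequency_map: 162 vertices, 200 patients, max count 57

vw <- vertexwise_inference(sim$cohort, sim$masks, factor_spec(),
                           n_perm = 200, seed = 1)
vw$map_level
#>              factor observed threshold significant
#> 1               sex        7  37.10000       FALSE
#> 2      age_at_onset      107  42.02500        TRUE
#> 3          duration        3  33.00000       FALSE
#> 4 ever_mri_negative       14  34.70833       FALSE
#> 5   lesion_size_pct      156  38.05000        TRUE
#> 6 lesion_hemisphere       32  38.70833       FALSE
```

The generator plants an onset-age coupling along a smooth cortical axis
by default, and the permutation procedure recovers it (the lesion-size
association is intrinsic: larger lesions cover more vertices). The
onset-by-location map correlates with the axis under the spin test:

```r
onset_map <- mean_value_map(sim$cohort, sim$masks, "age_at_onset")
filled <- onset_map$mean
filled[is.na(filled)] <- mean(filled, na.rm = TRUE)
spin_correlation_test(filled, axis_map(mesh), mesh,
                      n_rotations = 500, seed = 2)
#> spin_test: r_rank = 0.927, p_spin = 0.005988 (500 rotations)
```

The presurgical outcome model recovers the planted eloquent-overlap
effect (−1.39) and translates it into a probability drop:

```r
fit <- fit_outcome_model(sim$cohort, outcome_model_spec("presurgical"))
fit$coefficients[["eloquent_overlap"]]
#> [1] -1.455665
round(crossvalidate(sim$cohort, outcome_model_spec("presurgical"),
                    seed = 3)$metrics, 2)
#> sensitivity specificity         ppv         npv
#>        0.84        0.38        0.69        0.59
100 * predicted_probability(-1.39, 0.70, 0.5)   # 50% eloquent overlap
#> [1] 53.8001
```

A baseline 70% chance of seizure freedom falls to ~54% at 50% overlap
with eloquent cortex — a 16-point drop.

`run_pipeline(run_config(out_dir = "out"))` executes all stages on a
simulated cohort and writes atlases (plain-text vertex maps + NIfTI),
the stability table and learning curve, verdict tables, model reports
and a JSON run report.

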