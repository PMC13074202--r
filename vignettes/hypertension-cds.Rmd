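---
title: "Hybrid stratification and rule-based lifestyle recommendations for hypertension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid stratification and rule-based lifestyle recommendations for hypertension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htncds)
```

## The problem and the model

Primary-care hypertension cohorts are clinically heterogeneous: a single
guideline-driven recommendation scheme either over-treats low-risk
patients or under-serves high-risk ones. `htncds` couples two classical
components into one auditable system:

1. **Unsupervised stratification.** Patients are embedded by PCA over 15
   standardized cardiometabolic and behavioral measurements and grouped
   with a clustering model selected over an algorithm × k grid by internal
   validity indices. Clusters act as *contexts*, not as diagnoses.
2. **Rule-based inference with dual weighting.** Six intervention domains
   (physical activity, stress management, nutrition, sleep, therapeutic
   adherence, general health behaviors) each carry a small set of
   conjunctive threshold rules and a fallback level. Per-domain rule
   scores are computed for the individual patient and for the patient's
   cluster centroid ("virtual patient"), then blended as
   `score = α·individual + β·cluster` with `α = 0.85`, `β = 0.15`. The
   argmax level is returned with the fired-rule trace, so any
   recommendation can be re-derived by hand.

The combination rule is a *convex combination of normalized per-level
scores*. That realization is one of several consistent with a
"dual-weighting" description; we chose it because it is the simplest
mechanism with the right limits — `β = 0` reproduces a rules-only system
exactly, and `β = 1` makes recommendations constant within clusters (both
limits are asserted by the test suite). Whether scores are normalized
before weighting is exposed via `evaluate_individual(..., normalize =)`.

### Assumptions

- Clustering variables are continuous and roughly elliptical per subgroup;
  categorical structure influences recommendations, never cluster
  geometry (mixed-type clustering was deliberately avoided — with mostly
  continuous clinical measurements, Gower-style metrics dilute the
  cardiometabolic signal).
- Rule inputs are complete after preprocessing; the engine refuses to
  score a patient with a missing referenced variable rather than guess.
- Expert validation is a two-rater comparison (system vs panel
  consensus), so Cohen's κ, not a multi-rater generalization, is the
  right agreement statistic.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `max_missing_fraction` | 0.5 (strict >) | fraction | "more than half missing" is the removal phrase; a row at exactly 0.5 is kept |
| `knn_k` | `"sqrt"` → round(√n) | neighbors | square-root heuristic; 25 at n = 615 |
| `meters_cutoff` | 3.0 | m/cm boundary | no adult height is ambiguous across 3 under either unit |
| `tau` | 0.90 | variance fraction | retain ≥ 90% of standardized variance; boundary inclusive |
| `k_range` | 3–6 | clusters | the grid actually searched during method development; wider grids are one argument away |
| `alpha` / `beta` | 0.85 / 0.15 | weights | prioritizes patient-specific evidence while keeping group context; robustness to β ∈ [0.10, 0.25] is a tested property |
| `n_cases`, `raters`, `echo` | 120, 5, 0.8 | — | validation-panel geometry: 120 stratified cases, five raters, majority ≥ 3 |

All rule thresholds live in `inst/extdata/default_rules.yaml`, never in
code. They are implementation-chosen, anchored to widely used clinical
cut-points (BP control < 130/80 mmHg; prediabetic glucose ≥ 100 mg/dL;
cholesterol ≥ 200 mg/dL; triglycerides ≥ 150 mg/dL; overweight
BMI ≥ 25; adult sleep window 7–9 h). Local deployments are expected to
re-parameterize the file; the loader re-validates everything against the
schema and the fixed domain taxonomies.

## What the synthetic cohort emulates — and what it does not

`default_study_config()` plants three phenotypes in a 623-patient,
52-variable cohort:

- **metabolic–hypertensive** (n = 352): glucose 110.24 mg/dL, age 51.19 y,
  weight 70.31 kg, activity 2.64 d/wk, BP 142.06/88.65 mmHg, hemoglobin
  14.08 g/dL, eGFR 81.31, cholesterol 191.72, triglycerides 130.88;
- **dyslipidemic–anemic** (n = 264): cholesterol 214.85, glucose 93.40,
  age 55.90, weight 65.83, activity 2.35, hemoglobin 12.67, eGFR 77.39;
- **constitutional–atypical** (n = 7): height 181 cm, weight 79.29,
  glucose 111.03, hemoglobin 14.70, diastolic 89.43.

Variables without a phenotype-specific value take one shared cohort-level
reference (blood-pressure and activity references are cohort means; the
rest are mid-range clinical values chosen once, documented in
`shared_reference_means()`), so numeric separation comes only from the
phenotype-defining coordinates. Noise is Gaussian, independent across
variables, with SD = 5% of each mean. Missingness is MCAR at 0.30 per
cell (magnitude was reported for the motivating data; the mechanism was
not, and MCAR is the testable default). 314 of 623 heights are emitted in
meters. Phenotype-linked *categorical* contrasts (smoking prevalence,
adherence, sex composition) are encoded in the per-profile category
distributions; they drive recommendation contrasts but never enter
clustering.

Real cohorts differ in ways that matter:

- **Within-group correlation.** Real cardiometabolic variables are
  strongly correlated, which is why PCA compresses real data hard (a
  dominant first component) while the synthetic cohort — independent
  within profile — needs ~12 of 15 components to reach 90%. Passing tests
  therefore validate the pipeline's mechanics, not PCA's compression
  behavior on real data.
- **Cluster geometry.** Planted subgroups are spherical Gaussians; real
  phenotypes are skewed and overlapping.
- **Missingness mechanism.** MCAR only; imputation bias under MAR/MNAR is
  out of scope.

### What a sum-of-squares objective can and cannot recover here

The recovery experiment (`recovery_experiment()`, also the core of
`scripts/acceptance.R`) shows a structural property worth understanding
before interpreting its output. With profile sizes 352/264/7 and
independent 5%-of-mean noise, the 7-patient atypical profile sits about
3–4 within-cluster standard deviations from the dominant profile in the
retained PCA space. Assigning those 7 points to the nearest large cluster
costs the k-means objective roughly `7·d² ≈ 80–290` units, while *splitting*
the 352-patient profile along any of its several isotropic directions
gains roughly `0.64·352 ≈ 225` or more. The sum-of-squares optimum at
k = 3 therefore splits the dominant phenotype instead of isolating the
atypical one — an instance of the well-known size-imbalance pathology of
k-means — and a tiny planted subgroup would need ≳ 6.5σ separation to
survive. Consequently:

- the matched-cluster **centroid coordinates** (glucose, cholesterol,
  age) are recovered to within ~2%, because the split halves inherit the
  dominant profile's means and the 264-patient profile stays intact;
- the recovered **cluster sizes** do not reproduce 352/264, and the
  package reports the sizes it actually finds. The corresponding
  acceptance check is deliberately left failing rather than re-tuned,
  because the generator's noise scale and shared-reference design are
  part of the study conditions, not free dials.

In the motivating real data the atypical subgroup was reported as stable
across initializations — plausible there because correlated real
variables concentrate within-cluster variance in few directions, which
simultaneously shrinks the split gain and sharpens the subgroup's
separation. The synthetic cohort, by design, does not manufacture that
extra structure.

## Numerical choices

- **Population-sd z-scores** (denominator n): standardization is a
  transform, not an estimator; one convention had to be fixed.
- **PCA sign convention:** each component's largest-magnitude loading is
  made positive, so loadings and scores are reproducible across BLAS
  builds.
- **Retention boundary:** cumulative ratio ≥ τ is inclusive (a component
  landing exactly on 0.90 is kept), with a 1e-12 guard against float
  drift.
- **Partial-distance KNN:** distances use mutually observed z-scaled
  coordinates rescaled by √(p_total/p_obs); rows missing the target
  variable are excluded as donors; observed cells are never overwritten.
- **Mode ties** break by schema category order and are logged.
- **Silhouette conventions:** singletons get s = 0; a = 0 with b > 0
  gives s = 1 (the formula is undefined there).
- **Davies–Bouldin / Calinski–Harabasz degeneracies** (coincident
  centroids, zero within-scatter) propagate as `Inf` with a warning
  instead of failing.
- **Calinski–Harabasz normalization** is the standard (k−1, n−k)
  degrees-of-freedom form.
- **Selection total order:** max silhouette, then max CH, then min DB —
  "jointly analyzed" needs a deterministic tie-breaking order to be
  reproducible.
- **k-means:** k-means++ seeding, Lloyd iterations, 10 restarts, best
  inertia; empty clusters trigger one re-seeded retry, then an error.
- **Recommendation ties** resolve to the higher urgency rank, then
  alphabetically — clinically conservative and deterministic.
- **Consensus:** majority is ≥ 3 of 5; below that, plurality; a full
  plurality tie is broken toward urgency and flagged, and flagged cases
  are excluded from agreement statistics (the motivating description
  alternates between "at least three" and "at least two" supporters; we
  implement ≥ 3 with a logged plurality fallback).
- **Kappa CI:** κ ± 1.96·√(p₀(1−p₀)/(n(1−p_e)²)), clipped to [−1, 1];
  the pooled "overall" κ treats all (case, domain) pairs as one table,
  and the overall chi-square sums per-domain statistics and degrees of
  freedom.

## Problem sizes

The test suite exercises the full 623-patient cohort for pipeline-level
properties, ≤ 30-point instances against brute-force index oracles
(100 random instances in the acceptance suite), n = 10⁴ draws for the
independence check of κ, and 1 000 cases for the consensus-recovery
check; ten seeds for the phenotype-recovery experiment. These sizes give
sampling error comfortably below every asserted tolerance while keeping
a full run in tens of seconds.

## Known limitations

- Rule thresholds are a structural reconstruction, not a clinically
  validated table; deploying them without local calibration would be
  wrong.
- The adherence domain keys on medication status and BP control; in a
  cohort where almost nobody meets the BP target, "urgent" dominates —
  informative about the cohort, but blunt as an individual discriminator.
- Recommendations are cross-sectional; longitudinal updating and EHR
  integration are out of scope.
- The simulated rater panel models independent per-rater noise around the
  system's own labels; it validates the agreement *machinery*, not
  clinical correctness.
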