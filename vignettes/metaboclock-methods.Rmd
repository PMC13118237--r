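---
title: "Methods: the metabolomic aging clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the metabolomic aging clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboclock)
```

## Overview

`metaboclock` estimates a person's *biological (metabolic) age* from a
direct-infusion mass-spectrometry (DIMS) fingerprint — the vector of peak
intensities of one blood sample, used without metabolite identification —
and, more importantly, the *change* of that age between two samplings of the
same person. The method rests on a sex-specific **age-related metabolomic
curve** built from a cross-sectional cohort, and on a nearest-reference
search along that curve.

The pipeline is:

1. **Ingestion** (`read_peaklist()`, `recalibrate()`,
   `apply_intensity_thresholds()`): centroided peak lists are recalibrated
   against the losartan internal standard (m/z 423.169) by a single
   multiplicative scale — one internal standard supports exactly one degree
   of freedom — and filtered by a relative (0.01% of the base peak) and an
   absolute (100 counts) intensity threshold.
2. **Alignment** (`align_spectra()`): peaks of all spectra are pooled,
   sorted by m/z, and clustered greedily against a running centroid with a
   ppm tolerance (default 10 ppm); adjacent clusters closer than twice the
   tolerance whose across-sample intensity patterns correlate above 0.8 are
   then merged iteratively. Each cluster is a feature; absent peaks are
   zeros. Total intensity is conserved by construction.
3. **Curve building** (`train_age_model()`): per sex, features present in at
   least 15% of samples are tested for Spearman correlation with
   chronological age; p-values are FDR-adjusted (Benjamini–Hochberg by
   default) and features with adjusted p < 0.01 retained. Retained
   intensities are z-scored (training mean and SD are stored), smoothed over
   age with a ±3-year moving window, and summarized two ways: the
   **Z̄-score curve** (per-subject feature-mean, same-age subjects averaged,
   cubic smoothing spline over age), and the **reference matrix** of
   per-feature smoothed trajectories evaluated on a 1-year age grid — one
   reference fingerprint per grid age.
4. **Estimation** (`estimate_age()`): a new sample is z-scored with the
   stored parameters; the Euclidean distance to every reference fingerprint
   forms the distance profile; the grid minimum is refined by the vertex of
   the parabola through the minimum and its two neighbours, clamped to the
   bracketing interval. Biological-age change is the difference of two such
   estimates (`delta_bioage()`), reported in years and days (365.25 d/y).
5. **Validation and precision** (`validate_clock()`, `repro_metrics()`,
   `mdc()`): changes in biological age for longitudinal pairs are regressed
   on changes in chronological age (leave-one-out: each pair's subject is
   excluded from the training set before its curve is built); technical
   replicates yield SD, SEM = SD/√n, MAD (mean absolute deviation from the
   replicate mean) with a seeded percentile-bootstrap 95% CI, and the
   minimum detectable change MDC = 1.96·√2·SEM.
6. **Network biomarkers** (`node_degrees()`, `select_central()`): given a
   metabolite–metabolite interaction network as an edge list, the
   highest-degree nodes are selected as biomarkers of metapathway state
   (BMS), ties broken alphabetically for determinism.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `ref_mz` | 423.169 | Da | internal-standard mass (losartan) |
| `tol_ppm` (recalibration) | 20 | ppm | search window for the standard |
| `rel_pct`, `abs_min` | 0.01, 100 | %, counts | intensity thresholds |
| `tol_ppm` (alignment) | 10 | ppm | clustering tolerance |
| `corr_threshold` | 0.8 | – | merge gate for split peaks |
| `min_nonzero_frac` | 0.15 | – | eligibility screen (missingness guard) |
| `alpha` | 0.01 | – | adjusted-p selection threshold |
| `half_window_years` | 3 | years | trajectory smoothing window |
| age grid | 1-year steps | years | curve resolution |

The 20 ppm recalibration window is a configurable default: it must admit
the instrument's worst mass drift while excluding neighbouring analytes.
The alignment algorithm is a deterministic, testable surrogate for
correlation-pattern-based DIMS alignment; its exact original iteration rules
are not published, so we implement the stated idea (ppm clustering plus a
correlation-gated merge) in a reproducible form. On well-separated clusters
(tight within a quarter of the tolerance, separated by more than four times
the tolerance) the greedy pass provably coincides with exhaustive
single-linkage clustering at the same cut, which is how the tests oracle it.

## Design decisions in the open points

**FDR method.** Benjamini–Hochberg is the default (conservative,
parameter-free); Storey's pFDR — the default of some spectrometry toolchains
— is available via `fdr_method = "storey"` with a fixed-lambda π₀ estimate.

**Spearman p-values.** BH selection at α = 0.01 over thousands of features
is decided by p-values of order 10⁻⁵, where the common t approximation on
rank correlations is measurably liberal (its 10⁻⁵ tail holds ≈ 1.75 × 10⁻⁵
of the null mass at n = 40). Tie-free features tested against tie-free ages
(n < 1290) therefore use the exact/Edgeworth null of `cor.test`; tied data —
zero-inflated intensities, repeated integer ages — fall back to the
vectorized t approximation, the standard treatment for tied ranks. The
family-wise null-control property is consequently exact on tie-free cohorts
and mildly anti-conservative under heavy zero-inflation.

**Spline.** `stats::smooth.spline` with smoothing chosen by generalized
cross-validation, overridable via `spline_spar`. Fewer than four distinct
ages fall back to linear interpolation, where a smoothing spline is not
defined.

**Reference fingerprints.** The per-feature per-age means of smoothed
z-scores are carried onto the grid by the *same smoothing spline* as the
Z̄ curve (`reference_interp = "spline"`, the default), so reference
fingerprints are points on smooth per-feature trajectories. Raw linear
interpolation of the per-age means is available (`"linear"`) but transfers
the sampling irregularity of the cohort's age distribution — one to three
subjects per age in realistic cohorts — straight into the reference
fingerprints, where it appears as a year-scale warp shared by all features
and therefore does not average out across features. This choice is the
central interpretive decision of the curve module: the distance search is
meant to run against points on a *curve*, not against re-noised per-age
averages.

**Vertex refinement.** "Three points forming the minimum" is implemented as
the unique interpolating parabola's vertex,
x* = x₁ + h(y₀ − y₂) / (2(y₀ − 2y₁ + y₂)), clamped to the bracketing
interval; a boundary minimum returns the boundary age flagged
`at_boundary`. Ties break toward the younger age and are flagged. The
closed form doubles as an independent oracle in the tests.

**MDC.** The test–retest literature defines MDC at 95% confidence as
1.96·√2·SEM; the √2 reflects that a change is a difference of two
measurements. A reported SEM of 10 days gives MDC = 27.7 days, matching the
reliability figures this method is known for. The literal factor 2
(`literal_x2 = TRUE`) is kept for comparability, giving 39.2 days for the
same SEM.

**MAD.** Defined as the mean absolute deviation of replicate estimates from
their mean; the mean absolute pairwise difference is available via
`mad_method = "pairwise"`. The bootstrap CI uses seeded percentile
resampling. An optional outlier rule (|value − median| > 3 × scaled MAD) is
off by default and reports exclusions.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline assumes,
with full ground truth, so every stage is testable without any external
download:

* **Ages** cover the cohort range (default 18–81) evenly within each sex
  (shuffled round-robin), emulating designed recruitment for curve-building
  cohorts rather than convenience sampling. Uneven coverage leaves holes
  whose window-weighting warp is shared across features and visibly distorts
  the reference curve.
* **Intensities** are log-normal: per-feature baseline log-intensity
  ~ N(log 10⁴, 1), plus the age trajectory, plus technical noise
  (`noise_sd`, log scale), exponentiated; `dropout_prob` zeroes entries
  (missing peaks), optionally intensity-dependently.
* **Trajectories**: a fraction `frac_age_assoc` (default 0.3) of features is
  age-associated, split 70/30 between *linear* trends and *wave*
  trajectories — a logistic transition centred at 50 years (men) / 47 years
  (women) with a 3-year scale, mimicking the mid-life phase change of the
  blood metabolome.
* **Effect size** is expressed in z-units: the amplitude is calibrated so
  that a linear trajectory spans `effect_size` z-scores after
  standardization in a cohort with reference technical noise
  (`ref_noise_sd` = 0.3 log-units, a typical ~30% DIMS CV). The amplitude is
  independent of the cohort's actual `noise_sd`, so recovery error falls as
  noise falls; the realized span saturates at √12 ≈ 3.46 z-units as noise
  vanishes, hence `effect_size < 3.46`.
* **Subjects** carry a persistent per-feature offset (`subject_sd` = 0.1
  log-units): between-subject variation at fixed age. This offset puts every
  individual's fingerprint at a distance floor from the population curve —
  making the distance minimum locally quadratic, which the parabolic
  refinement needs — and cancels exactly between two samples of the same
  subject, which is what makes sub-year *changes* measurable even though
  single estimates carry year-scale error.
* **Longitudinal follow-ups** (`simulate_followups()`) re-sample chosen
  subjects after 3/6/12/18-month gaps (configurable `aging_rate`), with
  fresh technical noise and dropout but the same subject offset.
  **Technical replicates** (`simulate_replicates()`) re-acquire one sample
  with replicate noise only — no age shift, no dropout re-draw — so zero
  replicate noise yields byte-identical spectra.

What the generator does **not** emulate: batch and instrument drift,
correlated features (isotopes, adducts of one metabolite), chromatography,
intensity-dependent noise heteroscedasticity beyond the optional dropout
rule, and non-uniform population age structure. Passing recovery tests on
this generator therefore demonstrates the pipeline's statistical
correctness under its own assumptions, not performance on any real cohort.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script use: recovery cohorts of 250
subjects × 3000 features (200 train / 50 held out; technical noise 0.3 with
10% dropout, and a noise-free variant); a clock cohort of 190 subjects over
ages 18–66 with 60 follow-up pairs at 3/6/12/18-month gaps under low
technical noise (0.02) and leave-one-out retraining; 500 null cohorts of 40
subjects × 1000 features for the FDR control; and 1000 random 3-point
neighbourhoods for the vertex oracle. Follow-up subjects are drawn with
baseline ages 21–54 inside the 18–66 curve range, mirroring how
longitudinal validation subjects are recruited inside a curve cohort's age
span: estimates of subjects at the grid edge are clamped to the boundary
and carry no sub-year information.

## Known limitations

* Absolute biological age is only defined relative to the training cohort's
  curve; cross-cohort calibration is out of scope.
* Estimates at the ends of the age grid are boundary-clamped; changes for
  subjects near the edges are compressed.
* The ±3-year smoothing slightly flattens sharp mid-life transitions, which
  biases the local slope of estimated-vs-true age below 1 near the wave; in
  clock validation this appears as regression slopes somewhat below unity.
* The alignment surrogate is faithful to the published *idea* but not to
  unpublished implementation details of the original alignment tool.
* Family-wise false-selection control is exact for tie-free data; rank ties
  from zero-inflated intensities push the deep-tail p-values of the
  t approximation slightly low, so the realized family-wise rate on heavily
  zero-inflated null data can exceed the nominal α by a factor of about two
  at α = 0.01.
* With very low between-subject and technical variation, distance profiles
  become V-shaped at the minimum and the parabola vertex under-resolves
  sub-grid positions; this regime does not arise in real fingerprint data.
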