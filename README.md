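# metaboclock

A metabolomic aging clock for direct-infusion mass-spectrometry (DIMS)
fingerprints of blood. The package builds sex-specific age-related
metabolomic curves from peak-intensity matrices, estimates an individual's
biological (metabolic) age with sub-year resolution, quantifies how
precisely a *change* in biological age can be detected, and selects
degree-central metabolites of an interaction network as biomarkers of
metapathway state (BMS). It is aimed at metabolomics groups running DIMS
fingerprinting of plasma or dried blood spots who want a reproducible,
testable implementation of the whole chain from peak lists to
minimum-detectable-change statistics.

## The method

For a training cohort of one sex, peaks with non-zero intensity in ≥ 15% of
spectra are screened by Spearman correlation with chronological age and kept
at FDR-adjusted *p* < 0.01 (Benjamini–Hochberg). Each retained peak is
standardized to a Z-score, *z* = (x − μ)/σ, and smoothed over age with a
±3-year moving window. Per subject, the mean over peaks gives the Z̄-score;
same-age subjects are averaged and a cubic smoothing spline of Z̄ versus age
yields the **age-related metabolomic curve** on a 1-year grid, with one
smoothed reference fingerprint per grid age.

For a new fingerprint z, the Euclidean distance
d(a) = ‖z − ref(a)‖ is computed at every grid age a. Biological age is the
minimum of the distance curve, refined by the vertex of the parabola through
the three points around the minimum:

    a* = a₁ + h (d₀ − d₂) / (2 (d₀ − 2d₁ + d₂))

Change in biological age is the difference of two estimates. Precision is
summarized from technical replicates as SD, SEM = SD/√n, MAD (with a
bootstrap 95% CI), and the minimum detectable change
**MDC = 1.96 · √2 · SEM**, so e.g. SEM = 10 days ⇒ MDC ≈ 27.7 days.
Validity is checked by the "metabolic clock" test: regressing
biological-age change on chronological-age change for longitudinal pairs,
with each pair's subject excluded from curve training (leave-one-out).

A fully seeded synthetic-cohort generator (`simulate_cohort()`,
`simulate_followups()`, `simulate_replicates()`) provides ground-truth data
with realistic structure (log-normal intensities, linear and mid-life "wave"
trajectories changing near 47–50 years, zero-inflation, technical noise,
persistent per-subject fingerprint offsets), so the entire pipeline is
testable offline.

## Worked example

```r
library(metaboclock)

## simulate a cohort: 250 subjects, 3000 peaks, ages 18-81
cfg <- sim_config(n_subjects = 250, n_features = 3000, seed = 1)
sim <- simulate_cohort(cfg)
train <- subset_samples(sim$matrix, 1:200)
test  <- subset_samples(sim$matrix, 201:250)

## build the male curve and estimate a held-out male subject
model <- train_age_model(train, sex = "male")
model
#> age_curve_model (male): 907 features, grid 18-80 y, 96 training samples

i <- which(test$samples$sex == "male")[1]
est <- estimate_age(model, test$intensities[i, ], feature_mz = test$feature_mz)
est
#> biological age: 63.36 years
test$samples$age[i]
#> [1] 64

## technical replicates of one plasma sample -> precision of the estimate
reps <- simulate_replicates(sim, subject_id = "SUBJ0002", n = 10, seed = 2)  # male, 54 y
ests <- apply(reps$intensities, 1, function(x) estimate_age(model, x)$bio_age)
repro_metrics(ests, seed = 3)
#> repro_metrics (n = 10): SD 21.2 d, SEM 6.7 d, MAD 13.1 d (95% CI 4.0-26.7), MDC 18.6 d

## central-node biomarkers from a metabolite network
net <- read_edge_list(system.file("extdata", "example_network.tsv",
                                  package = "metaboclock"))
select_central(node_degrees(net), top_k = 3)
```

The estimate (63.4 y for a 64-year-old) reflects single-sample error of
roughly a year; the replicate statistics say how reliably *changes* can be
read: with an SEM of ~7 days, only biological-age changes larger than the
MDC (~19 days here) exceed measurement noise at 95% confidence.

A thin command-line interface wrapping the same functions ships in
`inst/exec/metaboclock` (subcommands `ingest`, `align`, `build-curve`,
`estimate`, `delta`, `metrics`, `bms`, `simulate`).

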