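toy_model <- function(reference_matrix, age_grid) {
  structure(
    list(sex = "male", age_grid = as.integer(age_grid),
         params = structure(list(feature_index = seq_len(nrow(reference_matrix)),
                                 feature_mz = 100 + seq_len(nrow(reference_matrix)),
                                 mean = rep(0, nrow(reference_matrix)),
                                 sd = rep(1, nrow(reference_matrix))),
                            class = "zscore_params"),
         reference_matrix = reference_matrix,
         zbar_curve = colMeans(reference_matrix),
         zbar_points = NULL, spline = list(), provenance = list()),
    class = "age_curve_model")
}

test_that("distance_profile computes Euclidean distances per grid age", {
  ref <- cbind(c(0, 0), c(4, 5), c(1, 1))
  model <- toy_model(ref, 40:42)
  prof <- distance_profile(model, c(1, 1))
  expect_s3_class(prof, "distance_profile")
  expect_length(prof$distances, 3)
  expect_equal(prof$distances[2], 5)          # 3-4-5 triangle
  expect_equal(prof$distances[3], 0)          # self-distance
  expect_error(distance_profile(model, c(1, 1, 1)), "mismatch")
})

test_that("translation of sample and references leaves the profile unchanged", {
  set.seed(31)
  ref <- matrix(rnorm(5 * 7), 5, 7)
  z <- rnorm(5)
  shift <- rnorm(5)
  m1 <- toy_model(ref, 30:36)
  m2 <- toy_model(ref + shift, 30:36)
  expect_equal(distance_profile(m1, z)$distances,
               distance_profile(m2, z + shift)$distances)
})

test_that("estimate_bioage finds the parabolic vertex of the distance minimum", {
  expect_equal(estimate_bioage(toy_profile(c(2, 1, 2)))$bio_age, 31)
  est <- estimate_bioage(toy_profile(c(2, 1, 1.5)))
  expect_equal(est$bio_age, 31 + 0.5 / 3, tolerance = 1e-12)   # 31.1667
  expect_false(est$at_boundary)
})

test_that("boundary minima return the boundary age, flagged", {
  est <- estimate_bioage(toy_profile(c(1, 2, 3, 4), ages = 18:21))
  expect_equal(est$bio_age, 18)
  expect_true(est$at_boundary)
  est2 <- estimate_bioage(toy_profile(c(4, 3, 2, 1), ages = 18:21))
  expect_equal(est2$bio_age, 21)
  expect_true(est2$at_boundary)
})

test_that("degenerate profiles are rejected; ties break young and are flagged", {
  expect_error(estimate_bioage(toy_profile(c(1, 1, 1))), "flat")
  expect_error(estimate_bioage(toy_profile(c(1, 2))), "3 grid points")
  est <- estimate_bioage(toy_profile(c(2, 1, 5, 1, 2)))
  expect_true(est$tie)
  expect_lt(est$bio_age, 32)   # younger minimum chosen
})

test_that("interior estimates equal the closed-form vertex for random neighbourhoods", {
  set.seed(32)
  for (rep in 1:1000) {
    y1 <- runif(1, 0, 5)
    y0 <- y1 + runif(1, 0.01, 3)
    y2 <- y1 + runif(1, 0.01, 3)
    pad_l <- y0 + runif(1, 0.1, 2)   # keep the argmin interior
    pad_r <- y2 + runif(1, 0.1, 2)
    prof <- toy_profile(c(pad_l, y0, y1, y2, pad_r), ages = 40:44)
    est <- estimate_bioage(prof)
    expect_equal(est$bio_age, parabola_vertex(42, 1, y0, y1, y2),
                 tolerance = 1e-9)
  }
})

test_that("delta_bioage converts years to days and is antisymmetric", {
  prof <- toy_profile(c(2, 1, 2))
  base <- estimate_bioage(prof)
  e1 <- base; e1$bio_age <- 35.0
  e2 <- base; e2$bio_age <- 35.2
  d <- delta_bioage(e1, e2)
  expect_equal(d$delta_years, 0.2)
  expect_equal(d$delta_days, 73.05)
  expect_equal(delta_bioage(e2, e1)$delta_days, -73.05)
  expect_equal(delta_bioage(e1, e1)$delta_years, 0)
  e3 <- estimate_bioage(toy_profile(c(2, 1, 2), ages = 50:52))
  expect_error(delta_bioage(e1, e3), "different models")
})

test_that("repro_metrics reproduces textbook dispersion statistics", {
  r <- repro_metrics(c(30.0, 30.1, 29.9), seed = 1)
  expect_equal(r$sd_days, 0.1 * 365.25)
  expect_equal(r$sem_days, 0.1 * 365.25 / sqrt(3))
  expect_equal(r$mad_days, mean(abs(c(0, 0.1, -0.1))) * 365.25)  # 24.35 d
  expect_equal(r$mad_days, 24.35, tolerance = 1e-4)
  expect_equal(r$mdc_days, 1.96 * sqrt(2) * r$sem_days)
  expect_length(r$mad_ci_95, 2)
  expect_true(r$mad_ci_95[1] <= r$mad_days + 1e-9)

  ident <- repro_metrics(rep(31.4, 5), seed = 1)
  expect_equal(ident$sd_days, 0)
  expect_equal(ident$sem_days, 0)
  expect_equal(ident$mad_days, 0)
  expect_equal(ident$mdc_days, 0)

  expect_error(repro_metrics(30), "at least 2")
})

test_that("repro_metrics bootstrap is seed-reproducible and outlier rule optional", {
  x <- c(30, 30.05, 29.95, 30.02, 33)   # one gross outlier
  a <- repro_metrics(x, seed = 7)
  b <- repro_metrics(x, seed = 7)
  expect_identical(a$mad_ci_95, b$mad_ci_95)
  cleaned <- repro_metrics(x, seed = 7, exclude_outliers = TRUE)
  expect_equal(cleaned$excluded, 5L)
  expect_lt(cleaned$sd_days, a$sd_days)
})

test_that("mdc applies the test-retest formula in both conventions", {
  expect_equal(mdc(10), 27.7, tolerance = 1e-3)
  expect_equal(mdc(10), 1.96 * sqrt(2) * 10)
  expect_equal(mdc(1), 2.772, tolerance = 1e-4)
  expect_equal(mdc(0), 0)
  expect_equal(mdc(10, literal_x2 = TRUE), 39.2)
  expect_error(mdc(-1), "non-negative")
  # identity mdc/sem = 1.96 sqrt(2) for any positive sem
  for (s in c(0.3, 5, 123)) expect_equal(mdc(s) / s, 1.96 * sqrt(2))
})

test_that("validate_clock recovers a perfect clock and flags degenerate designs", {
  cfg <- sim_config(n_subjects = 60, n_features = 400, age_range = c(25, 55),
                    noise_sd = 0.01, dropout_prob = 0, seed = 33)
  sim <- simulate_cohort(cfg)
  subj <- sim$truth$subjects
  ok <- subj$subject_id[subj$true_age >= 30 & subj$true_age <= 48]
  fu <- simulate_followups(sim, subjects = ok[1:6],
                           gaps_months = c(6, 12, 18), seed = 34)
  v <- validate_clock(sim$matrix, fu$matrix, leave_one_out = FALSE,
                      alpha = 0.05)
  expect_gt(v$r_squared, 0.8)
  expect_gt(v$slope, 0.6)
  # independently coded R^2 on the same table
  tab <- v$table
  fit <- lm(delta_bio_years ~ delta_chrono_years, data = tab)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((tab$delta_bio_years - mean(tab$delta_bio_years))^2)
  expect_equal(v$r_squared, 1 - ss_res / ss_tot)

  # constant chronological gap: undefined fit
  fu2 <- simulate_followups(sim, subjects = ok[1:4], gaps_months = 12, seed = 35)
  expect_error(validate_clock(sim$matrix, fu2$matrix, leave_one_out = FALSE,
                              alpha = 0.05),
               "constant")
  # too few pairs
  fu3 <- simulate_followups(sim, subjects = ok[1:2], gaps_months = c(6, 12),
                            seed = 36)
  expect_error(validate_clock(sim$matrix, fu3$matrix), "at least 3")
})
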