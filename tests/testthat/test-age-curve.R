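# hand-coded step-up Benjamini-Hochberg: independent oracle
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

test_that("BH adjustment matches the hand-coded step-up oracle", {
  expect_equal(bh_stepup(c(0.001, 0.02, 0.04)), c(0.003, 0.03, 0.04))
  set.seed(21)
  for (rep in 1:25) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_stepup(p))
  }
})

test_that("select_age_features reproduces BH-adjusted Spearman screening", {
  set.seed(22)
  n <- 50
  ages <- sample(20:70, n, replace = TRUE)
  x <- cbind(ages,                                  # rho exactly 1
             100 + rnorm(n),                        # null
             exp(rnorm(n)),                         # null
             1000 - 5 * ages + rnorm(n))            # strong negative
  fm <- toy_feature_matrix(x, ages = ages)
  sel <- select_age_features(fm, alpha = 0.01)
  expect_true(1 %in% sel$feature_index)
  expect_true(4 %in% sel$feature_index)
  expect_equal(sel$spearman_rho[sel$feature_index == 1], 1)
  expect_equal(sel$direction[sel$feature_index == 1], "positive")
  expect_equal(sel$direction[sel$feature_index == 4], "negative")
  expect_false(2 %in% sel$feature_index)

  # adjusted p equals the oracle applied to the eligible p-values
  all_sel <- select_age_features(fm, alpha = 1.01)
  expect_equal(all_sel$adjusted_p, bh_stepup(all_sel$p_value))
  expect_true(all(all_sel$adjusted_p >= all_sel$p_value))
})

test_that("sparse features are excluded before testing, whatever their correlation", {
  set.seed(23)
  n <- 40
  ages <- sort(sample(20:70, n, replace = TRUE))
  x <- matrix(rexp(n * 2, 1e-3), n, 2)
  x[, 2] <- 0
  x[1:4, 2] <- ages[1:4]          # non-zero in 10% of samples, rho = 1 there
  fm <- toy_feature_matrix(x, ages = ages)
  sel <- select_age_features(fm, min_nonzero_frac = 0.15, alpha = 1.01)
  expect_false(2 %in% sel$feature_index)
  expect_equal(attr(sel, "n_eligible"), 1L)
})

test_that("select_age_features rejects degenerate designs", {
  fm <- toy_feature_matrix(matrix(rexp(20), 10, 2), ages = rep(40, 10))
  expect_error(select_age_features(fm), "degenerate")
  fm2 <- toy_feature_matrix(matrix(rexp(10), 5, 2), ages = c(20, 30, 40, 50, 60))
  expect_error(select_age_features(fm2), "at least 10 samples")
})

test_that("z-scoring standardizes exactly and round-trips through apply_zscores", {
  x <- cbind(c(1, 2, 3), c(10, 50, 90))
  fm <- toy_feature_matrix(x, ages = c(20, 40, 60))
  sel <- data.frame(feature_index = 1:2)
  zs <- fit_zscores(fm, sel)
  expect_equal(zs$z_matrix[, 1], c(-1, 0, 1))
  expect_equal(colMeans(zs$z_matrix), c(0, 0))
  expect_equal(apply(zs$z_matrix, 2, sd), c(1, 1))

  # scoring training rows with stored params reproduces z_matrix
  expect_equal(apply_zscores(fm$intensities, zs$params), zs$z_matrix)
  # a sample at the training mean scores zero
  mu_full <- colMeans(fm$intensities)
  expect_equal(apply_zscores(mu_full, zs$params), c(0, 0))
})

test_that("zero-variance features are refused by name", {
  fm <- toy_feature_matrix(cbind(c(5, 5, 5), c(1, 2, 3)), ages = c(20, 40, 60))
  expect_error(fit_zscores(fm, data.frame(feature_index = 1:2)), "101.0000")
})

test_that("apply_zscores detects a foreign feature axis", {
  fm <- toy_feature_matrix(cbind(c(1, 2, 3), c(4, 5, 6)), ages = c(20, 40, 60))
  zs <- fit_zscores(fm, data.frame(feature_index = 1:2))
  expect_error(apply_zscores(c(1, 2), zs$params, feature_mz = c(500, 600)),
               "feature-axis mismatch")
})

test_that("moving-window smoothing follows the |age difference| <= h rule", {
  z <- matrix(c(0, 3, 6), 3, 1)
  # half-window 0: identity
  expect_equal(smooth_trajectories(z, c(24, 25, 26), 0), z)
  # isolated subjects: unchanged
  expect_equal(smooth_trajectories(z, c(20, 25, 30), 3), z)
  # all three within one window: every value is the mean
  expect_equal(smooth_trajectories(z, c(24, 25, 26), 3),
               matrix(3, 3, 1))
  # asymmetric membership
  sm <- smooth_trajectories(z, c(20, 22, 25), 3)
  expect_equal(sm[, 1], c(mean(c(0, 3)), mean(c(0, 3, 6)), mean(c(3, 6))))
})

test_that("smoothing never widens the value range and fixes constants", {
  set.seed(24)
  for (rep in 1:10) {
    n <- 30
    ages <- sample(20:60, n, replace = TRUE)
    z <- matrix(rnorm(n * 3), n, 3)
    sm <- smooth_trajectories(z, ages, 3)
    expect_true(all(sm <= max(z) + 1e-12) && all(sm >= min(z) - 1e-12))
    const <- matrix(5, n, 2)
    expect_equal(smooth_trajectories(const, ages, 3), const)
  }
})

test_that("build_age_curve reproduces a linear Z-bar exactly and averages same-age subjects", {
  ages <- c(20, 25, 30, 35, 40, 45, 50)
  z <- matrix((ages - 35) / 10, ncol = 1)
  fm <- toy_feature_matrix(matrix(1, length(ages), 1), ages = ages)
  params <- fit_zscores(toy_feature_matrix(matrix(ages, ncol = 1), ages = ages),
                        data.frame(feature_index = 1))$params
  model <- build_age_curve(z, fm$samples, params, half_window_years = 0)
  grid <- model$age_grid
  expect_equal(unname(model$zbar_curve), (grid - 35) / 10, tolerance = 1e-6)
  # reference matrix feature-mean equals the Z-bar curve on noiseless input
  expect_equal(unname(colMeans(model$reference_matrix)),
               unname(model$zbar_curve), tolerance = 1e-6)

  # same-integer-age subjects are averaged before the fit
  ages2 <- c(30, 30, 40, 50)
  z2 <- matrix(c(1, 3, 4, 6), ncol = 1)
  m2 <- build_age_curve(z2, toy_feature_matrix(matrix(1, 4, 1),
                                               ages = ages2)$samples,
                        params)
  expect_equal(m2$zbar_points$zbar[m2$zbar_points$age == 30], 2)
})

test_that("build_age_curve validates sex homogeneity and grid coverage", {
  samples <- toy_feature_matrix(matrix(1, 4, 1), ages = c(20, 30, 40, 50),
                                sexes = c("male", "male", "female", "male"))$samples
  params <- structure(list(feature_index = 1L, feature_mz = 101,
                           mean = 0, sd = 1), class = "zscore_params")
  expect_error(build_age_curve(matrix(0, 4, 1), samples, params), "per sex")
  ok <- toy_feature_matrix(matrix(1, 4, 1), ages = c(20, 30, 40, 50))$samples
  expect_error(build_age_curve(matrix(0, 4, 1), ok, params,
                               age_grid = 10:60),
               "outside the observed age range")
})

test_that("stability_report tracks threshold monotonicity and density", {
  set.seed(25)
  cfg <- sim_config(n_subjects = 60, n_features = 150, age_range = c(20, 60),
                    sex_ratio = 1, dropout_prob = 0, seed = 25)
  sim <- simulate_cohort(cfg)
  rep_ <- stability_report(sim$matrix, alphas = c(0.1, 0.01, 0.001))
  counts <- vapply(rep_, `[[`, integer(1), "n_features")
  alphas <- vapply(rep_, `[[`, numeric(1), "alpha")
  expect_true(all(diff(counts[order(-alphas)]) <= 0))
  # dropout-free matrix: all used features fully dense
  expect_true(all(vapply(rep_, `[[`, numeric(1), "nonzero_fraction") == 100))
  # single alpha reproduces the default model's feature count
  one <- stability_report(sim$matrix, alphas = 0.01)
  model <- train_age_model(sim$matrix, "male", alpha = 0.01)
  expect_equal(one[[1]]$n_features, length(model$params$feature_index))
  expect_equal(unname(one[[1]]$zbar_curve), unname(model$zbar_curve))
})

test_that("null cohorts rarely select any feature at the nominal alpha", {
  # family-wise false-selection control under permuted/absent signal
  set.seed(26)
  n_sim <- 120
  hits <- 0L
  for (i in seq_len(n_sim)) {
    cfg <- sim_config(n_subjects = 30, n_features = 200, frac_age_assoc = 0,
                      sex_ratio = 1, dropout_prob = 0, seed = 1000 + i)
    sim <- simulate_cohort(cfg)
    sel <- select_age_features(sim$matrix, alpha = 0.01)
    hits <- hits + (nrow(sel) > 0L)
  }
  rate <- hits / n_sim
  mc_sd <- sqrt(0.01 * 0.99 / n_sim)
  expect_lte(rate, 0.01 + 3 * mc_sd)
})

test_that("models serialize losslessly through JSON + CSV", {
  cfg <- sim_config(n_subjects = 40, n_features = 120, age_range = c(20, 60),
                    sex_ratio = 1, seed = 27)
  sim <- simulate_cohort(cfg)
  model <- train_age_model(sim$matrix, "male")
  f <- withr::local_tempfile(fileext = ".json")
  save_age_model(model, f)
  back <- load_age_model(f)
  expect_equal(back$age_grid, model$age_grid)
  expect_equal(back$params$mean, model$params$mean)
  expect_equal(back$reference_matrix, model$reference_matrix,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(back$zbar_curve), unname(model$zbar_curve))
  # estimates agree between original and reloaded model
  x <- sim$matrix$intensities[1, ]
  expect_equal(estimate_age(back, x)$bio_age, estimate_age(model, x)$bio_age)
})
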