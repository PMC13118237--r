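#' Select age-correlated features by Spearman correlation with FDR control
#'
#' Features are first screened for presence: only features with non-zero
#' intensity in at least `min_nonzero_frac` of the samples are eligible (the
#' missingness guard for zero-inflated direct-infusion matrices). For each
#' eligible feature, Spearman's rho against chronological age is computed
#' with a two-sided p-value, the p-values are FDR-adjusted, and features with
#' adjusted p below `alpha` are retained.
#'
#' P-values use the t approximation on rank correlations (df = n - 2); for
#' n <= 12 without ties the exact null distribution is used instead.
#'
#' @param fm A [feature_matrix()].
#' @param min_nonzero_frac Minimum fraction of samples with a non-zero
#'   intensity for a feature to enter testing (default 0.15).
#' @param alpha Adjusted-p selection threshold (default 0.01).
#' @param fdr_method `"bh"` (Benjamini-Hochberg, default) or `"storey"`
#'   (Storey's pFDR with fixed-lambda pi0 estimate).
#'
#' @return A `data.frame` of class `feature_selection` with columns
#'   `feature_index`, `feature_mz`, `spearman_rho`, `p_value`, `adjusted_p`,
#'   `direction` (`"positive"`/`"negative"`), ordered by `feature_index`.
#'   Attributes `n_eligible` and `n_tested_samples` record the screen.
#' @export
select_age_features <- function(fm, min_nonzero_frac = 0.15, alpha = 0.01,
                                fdr_method = c("bh", "storey")) {
  stopifnot(inherits(fm, "feature_matrix"))
  fdr_method <- match.arg(fdr_method)
  ages <- fm$samples$age
  if (nrow(fm$intensities) < 10L) {
    stop("need at least 10 samples to select age features", call. = FALSE)
  }
  if (length(unique(ages)) < 2L) {
    stop("degenerate design: all subjects have the same age", call. = FALSE)
  }
  nonzero_frac <- colMeans(fm$intensities > 0)
  eligible <- which(nonzero_frac >= min_nonzero_frac)
  if (!length(eligible)) {
    sel <- data.frame(feature_index = integer(0), feature_mz = numeric(0),
                      spearman_rho = numeric(0), p_value = numeric(0),
                      adjusted_p = numeric(0), direction = character(0))
    class(sel) <- c("feature_selection", "data.frame")
    attr(sel, "n_eligible") <- 0L
    attr(sel, "n_tested_samples") <- nrow(fm$intensities)
    return(sel)
  }
  ct <- spearman_age_test(fm$intensities[, eligible, drop = FALSE], ages)
  adj <- switch(fdr_method,
                bh = stats::p.adjust(ct$p, method = "BH"),
                storey = storey_qvalue(ct$p))
  keep <- which(!is.na(adj) & adj < alpha)
  sel <- data.frame(
    feature_index = eligible[keep],
    feature_mz = fm$feature_mz[eligible[keep]],
    spearman_rho = ct$rho[keep],
    p_value = ct$p[keep],
    adjusted_p = adj[keep],
    direction = ifelse(ct$rho[keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  sel <- sel[order(sel$feature_index), , drop = FALSE]
  rownames(sel) <- NULL
  class(sel) <- c("feature_selection", "data.frame")
  attr(sel, "n_eligible") <- length(eligible)
  attr(sel, "n_tested_samples") <- nrow(fm$intensities)
  sel
}

# Vectorized Spearman correlation of every column of `x` against `age`,
# with two-sided p-values. Constant columns get rho = 0, p = 1.
#
# Tail accuracy matters here: BH selection at alpha 0.01 over thousands of
# features lives on p-values of order 1e-5, where the t approximation on
# rank correlations is mildly liberal. For tie-free columns (and tie-free
# ages) with n < 1290 the exact/Edgeworth null of cor.test is used instead;
# tied data (zero-inflated intensities, repeated ages) fall back to the
# t approximation, the standard choice for tied ranks.
spearman_age_test <- function(x, age) {
  n <- nrow(x)
  rho <- numeric(ncol(x))
  p <- numeric(ncol(x))
  ra <- rank(age)
  rx <- apply(x, 2L, rank)
  if (!is.matrix(rx)) rx <- matrix(rx, nrow = n)
  ra_c <- ra - mean(ra)
  rx_c <- sweep(rx, 2L, colMeans(rx))
  denom <- sqrt(colSums(rx_c^2) * sum(ra_c^2))
  rho <- as.numeric(crossprod(rx_c, ra_c)) / denom
  rho[!is.finite(rho)] <- 0
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- pmin(1, 2 * stats::pt(-abs(tstat), df = n - 2))
  p[abs(rho) == 1] <- 0

  age_tied <- anyDuplicated(age) > 0L
  if (!age_tied && n >= 4L && n < 1290L) {
    no_ties <- apply(rx, 2L, anyDuplicated) == 0L
    for (j in which(no_ties)) {
      ct <- suppressWarnings(
        stats::cor.test(rx[, j], ra, method = "spearman", exact = TRUE))
      p[j] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}

# Storey q-values with a fixed-lambda pi0 estimate (monotone step-up).
storey_qvalue <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  if (pi0 <= 0) pi0 <- 1 / m
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- 1
  for (i in seq_along(o)) {
    idx <- o[i]
    rank_p <- m - i + 1L
    running <- min(running, pi0 * p[idx] * m / rank_p)
    q[idx] <- running
  }
  q
}

#' Convert selected features to Z-scores
#'
#' Standardizes each selected feature over the training samples: the data
#' minus the mean, divided by the (n - 1) standard deviation. Zero
#' intensities are standardized like any other value. The training mean and
#' sd per feature are returned for scoring held-out samples.
#'
#' @param fm A [feature_matrix()] (training cohort).
#' @param selection A selection from [select_age_features()].
#'
#' @return List with `z_matrix` (samples x selected features, per-column
#'   mean 0 / sd 1) and `params`, an object of class `zscore_params`
#'   (`feature_index`, `feature_mz`, `mean`, `sd`).
#' @export
fit_zscores <- function(fm, selection) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- selection$feature_index
  if (!length(idx)) stop("empty feature selection", call. = FALSE)
  x <- fm$intensities[, idx, drop = FALSE]
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad)) {
    stop(sprintf("zero-variance feature(s) cannot be z-scored: m/z %s",
                 paste(format_feature_mz(fm$feature_mz[idx[bad]]),
                       collapse = ", ")), call. = FALSE)
  }
  z <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
  params <- structure(
    list(feature_index = idx, feature_mz = fm$feature_mz[idx],
         mean = unname(mu), sd = unname(sdv)),
    class = "zscore_params"
  )
  list(z_matrix = unname(z), params = params)
}

#' Score new intensities with stored z-normalization parameters
#'
#' Restricts a full-axis intensity vector (or matrix of rows) to the
#' selected features and standardizes with the training mean and sd. Zero
#' (absent) intensities are standardized as the value 0, not dropped.
#'
#' @param intensities Numeric vector along the full feature axis, or a
#'   samples x features matrix, or a [feature_matrix()].
#' @param params `zscore_params` from [fit_zscores()].
#' @param feature_mz The m/z axis of `intensities` (taken from the
#'   `feature_matrix` automatically); must match the training axis.
#'
#' @return A z-score vector (or matrix) over the selected features.
#' @export
apply_zscores <- function(intensities, params, feature_mz = NULL) {
  stopifnot(inherits(params, "zscore_params"))
  if (inherits(intensities, "feature_matrix")) {
    feature_mz <- intensities$feature_mz
    intensities <- intensities$intensities
  }
  x <- if (is.matrix(intensities)) intensities else
    matrix(intensities, nrow = 1L)
  if (!is.null(feature_mz)) {
    if (length(feature_mz) < max(params$feature_index) ||
        any(abs(feature_mz[params$feature_index] - params$feature_mz) >
            1e-4 * 2)) {
      stop("feature-axis mismatch: intensities are not on the model's m/z axis",
           call. = FALSE)
    }
  } else if (ncol(x) < max(params$feature_index)) {
    stop("feature-axis mismatch: too few features for the stored selection",
         call. = FALSE)
  }
  z <- sweep(sweep(x[, params$feature_index, drop = FALSE], 2L, params$mean),
             2L, params$sd, `/`)
  if (nrow(z) == 1L && !is.matrix(intensities)) z <- drop(z)
  unname(z)
}

#' Smooth z-score trajectories over age
#'
#' For each sample i and feature j, the smoothed value is the mean of z over
#' all samples whose age lies within `half_window_years` of sample i's age
#' (a +-3-year moving average by default, truncated at the cohort edges).
#'
#' @param z_matrix Samples x features z-score matrix.
#' @param ages Chronological age (years) per sample (row).
#' @param half_window_years Half-width of the age window; 0 returns the
#'   input unchanged.
#'
#' @return Smoothed matrix of the same shape. Values never leave the range
#'   of the input column values (means of subsets).
#' @export
smooth_trajectories <- function(z_matrix, ages, half_window_years = 3) {
  z_matrix <- as.matrix(z_matrix)
  if (length(ages) != nrow(z_matrix)) {
    stop("'ages' must have one entry per row of 'z_matrix'", call. = FALSE)
  }
  if (half_window_years < 0) stop("negative window", call. = FALSE)
  if (half_window_years == 0) return(z_matrix)
  w <- abs(outer(ages, ages, `-`)) <= half_window_years
  w <- w / rowSums(w)
  w %*% z_matrix
}

#' Build a sex-specific age-related metabolomic curve model
#'
#' From smoothed z-scores of one sex's training samples: each subject's
#' Z-bar score is the mean of their smoothed z over the selected features;
#' subjects sharing the same integer age are averaged; a cubic smoothing
#' spline of Z-bar versus age is evaluated on a 1-year grid. Reference
#' fingerprints per grid age are built feature-wise by the same
#' smooth-then-average procedure, linearly interpolated onto the grid with
#' nearest-value extension at the ends.
#'
#' @param smoothed_z Samples x features smoothed z matrix
#'   ([smooth_trajectories()]).
#' @param samples Metadata `data.frame` (needs `age`, `sex`), one row per
#'   row of `smoothed_z`; all one sex.
#' @param params `zscore_params` from [fit_zscores()] (stored for scoring).
#' @param age_grid Integer year grid; default spans the observed ages.
#' @param spline_spar Optional smoothing parameter for
#'   [stats::smooth.spline()]; default `NULL` = generalized cross-validation.
#' @param reference_interp How per-feature per-age means are carried onto
#'   the grid: `"spline"` (default; same smoothing spline as the Z-bar
#'   curve, so reference fingerprints are points on smooth trajectories) or
#'   `"linear"` (raw interpolation of per-age means).
#' @param alpha,half_window_years Provenance fields recorded on the model.
#'
#' @return An object of class `age_curve_model`: `sex`, `age_grid`,
#'   `params`, `reference_matrix` (features x grid ages), `zbar_curve`,
#'   `zbar_points` (per-age mean Z-bar actually fit), `spline` settings and
#'   provenance.
#' @export
build_age_curve <- function(smoothed_z, samples, params,
                            age_grid = NULL, spline_spar = NULL,
                            reference_interp = c("spline", "linear"),
                            alpha = NA_real_, half_window_years = NA_real_) {
  reference_interp <- match.arg(reference_interp)
  smoothed_z <- as.matrix(smoothed_z)
  if (nrow(samples) != nrow(smoothed_z)) {
    stop("metadata/matrix row mismatch", call. = FALSE)
  }
  sex <- unique(samples$sex)
  if (length(sex) != 1L) {
    stop("curve models are built per sex; got mixed sexes", call. = FALSE)
  }
  ages <- samples$age
  age_int <- round(ages)
  if (length(unique(age_int)) < 2L) {
    stop("need at least 2 distinct integer ages", call. = FALSE)
  }
  if (is.null(age_grid)) {
    age_grid <- seq(min(age_int), max(age_int))
  }
  age_grid <- as.integer(age_grid)
  if (min(age_grid) < min(age_int) - 0.5 || max(age_grid) > max(age_int) + 0.5) {
    stop("age grid extends outside the observed age range", call. = FALSE)
  }

  zbar <- rowMeans(smoothed_z)
  ages_u <- sort(unique(age_int))
  zbar_by_age <- vapply(ages_u, function(a) mean(zbar[age_int == a]),
                        numeric(1))
  zbar_curve <- fit_smoothing_spline(ages_u, zbar_by_age, age_grid,
                                     spline_spar)

  # per-feature reference trajectories: per-age mean of smoothed z, carried
  # onto the grid by the same smoothing spline as the Z-bar curve (linear
  # interpolation available as reference_interp = "linear")
  by_age <- vapply(ages_u, function(a) {
    colMeans(smoothed_z[age_int == a, , drop = FALSE])
  }, numeric(ncol(smoothed_z)))
  by_age <- matrix(by_age, nrow = ncol(smoothed_z))  # features x ages_u
  reference_matrix <- t(apply(by_age, 1L, function(v) {
    if (length(ages_u) == 1L) return(rep(v, length(age_grid)))
    if (reference_interp == "spline") {
      fit_smoothing_spline(ages_u, v, age_grid, spline_spar)
    } else {
      stats::approx(ages_u, v, xout = age_grid, rule = 2)$y
    }
  }))
  dimnames(reference_matrix) <- list(format_feature_mz(params$feature_mz),
                                     age_grid)

  structure(
    list(sex = sex, age_grid = age_grid, params = params,
         reference_matrix = reference_matrix,
         zbar_curve = stats::setNames(zbar_curve, age_grid),
         zbar_points = data.frame(age = ages_u, zbar = zbar_by_age),
         spline = list(spar = spline_spar,
                       method = if (is.null(spline_spar)) "gcv" else "spar",
                       reference_interp = reference_interp),
         provenance = list(alpha = alpha,
                           half_window_years = half_window_years,
                           n_samples = nrow(smoothed_z),
                           n_features = ncol(smoothed_z))),
    class = "age_curve_model"
  )
}

# Cubic smoothing spline fit of y(x) evaluated on `grid`. GCV by default;
# with fewer than 4 distinct x values smooth.spline is not defined, so fall
# back to linear interpolation (rule 2 extends flat at the ends).
fit_smoothing_spline <- function(x, y, grid, spar = NULL) {
  if (length(x) < 4L) {
    return(stats::approx(x, y, xout = grid, rule = 2)$y)
  }
  fit <- if (is.null(spar)) {
    stats::smooth.spline(x, y)
  } else {
    stats::smooth.spline(x, y, spar = spar)
  }
  stats::predict(fit, as.numeric(grid))$y
}

#' @export
print.age_curve_model <- function(x, ...) {
  cat(sprintf(
    "age_curve_model (%s): %d features, grid %d-%d y, %d training samples\n",
    x$sex, length(x$params$feature_index), min(x$age_grid), max(x$age_grid),
    x$provenance$n_samples))
  invisible(x)
}

#' Train an age-curve model from a feature matrix in one call
#'
#' Convenience wrapper chaining [select_age_features()], [fit_zscores()],
#' [smooth_trajectories()] and [build_age_curve()] on the samples of one sex.
#'
#' @param fm A [feature_matrix()] (may contain both sexes; filtered).
#' @param sex `"male"` or `"female"`.
#' @param alpha Adjusted-p threshold for feature selection.
#' @param half_window_years Smoothing half-window (years).
#' @param min_nonzero_frac,fdr_method Passed to [select_age_features()].
#' @param age_grid,spline_spar Passed to [build_age_curve()].
#'
#' @return An `age_curve_model`.
#' @export
train_age_model <- function(fm, sex, alpha = 0.01, half_window_years = 3,
                            min_nonzero_frac = 0.15, fdr_method = "bh",
                            age_grid = NULL, spline_spar = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  sex <- match.arg(sex, c("male", "female"))
  fm <- subset_samples(fm, fm$samples$sex == sex)
  sel <- select_age_features(fm, min_nonzero_frac = min_nonzero_frac,
                             alpha = alpha, fdr_method = fdr_method)
  if (!nrow(sel)) {
    stop("no age-correlated features selected at alpha = ", alpha,
         call. = FALSE)
  }
  zs <- fit_zscores(fm, sel)
  sm <- smooth_trajectories(zs$z_matrix, fm$samples$age, half_window_years)
  build_age_curve(sm, fm$samples, zs$params, age_grid = age_grid,
                  spline_spar = spline_spar, alpha = alpha,
                  half_window_years = half_window_years)
}

#' Curve-stability report across selection thresholds
#'
#' Rebuilds the Z-bar curve at each adjusted-p threshold in `alphas` and
#' reports, per threshold, the number of selected features, the curve, and
#' the fraction of non-zero intensity entries among the features used — the
#' diagnostics for showing that curve shape is robust to the selection
#' threshold and to missing values.
#'
#' @param fm A [feature_matrix()] of one sex.
#' @param alphas Numeric vector of adjusted-p thresholds.
#' @param half_window_years,min_nonzero_frac,fdr_method,age_grid,spline_spar
#'   As in [train_age_model()].
#'
#' @return A list with one element per alpha: `alpha`, `n_features`,
#'   `nonzero_fraction` (percent), `zbar_curve`, `age_grid`.
#' @export
stability_report <- function(fm, alphas, half_window_years = 3,
                             min_nonzero_frac = 0.15, fdr_method = "bh",
                             age_grid = NULL, spline_spar = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), length(alphas) >= 1L)
  sex <- unique(fm$samples$sex)
  if (length(sex) != 1L) stop("stability_report expects one sex", call. = FALSE)
  lapply(sort(alphas, decreasing = TRUE), function(a) {
    model <- try(train_age_model(fm, sex, alpha = a,
                                 half_window_years = half_window_years,
                                 min_nonzero_frac = min_nonzero_frac,
                                 fdr_method = fdr_method, age_grid = age_grid,
                                 spline_spar = spline_spar), silent = TRUE)
    if (inherits(model, "try-error")) {
      return(list(alpha = a, n_features = 0L, nonzero_fraction = NA_real_,
                  zbar_curve = NULL, age_grid = NULL))
    }
    used <- model$params$feature_index
    list(alpha = a,
         n_features = length(used),
         nonzero_fraction = 100 * mean(fm$intensities[, used, drop = FALSE] > 0),
         zbar_curve = model$zbar_curve,
         age_grid = model$age_grid)
  })
}
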