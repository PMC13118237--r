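DAYS_PER_YEAR <- 365.25

#' Distance profile of a fingerprint against the age curve
#'
#' Euclidean distance (in z-units) between a z-scored fingerprint and the
#' model's reference fingerprint at every grid age.
#'
#' @param model An `age_curve_model` from [build_age_curve()] /
#'   [train_age_model()].
#' @param sample_z Z-score vector over the model's selected features
#'   ([apply_zscores()]).
#'
#' @return An object of class `distance_profile`: `age_grid`, `distances`.
#' @export
distance_profile <- function(model, sample_z) {
  stopifnot(inherits(model, "age_curve_model"))
  sample_z <- as.numeric(sample_z)
  if (length(sample_z) != nrow(model$reference_matrix)) {
    stop("feature-axis mismatch: z-vector length != model feature count",
         call. = FALSE)
  }
  d <- sqrt(colSums((model$reference_matrix - sample_z)^2))
  structure(list(age_grid = model$age_grid, distances = unname(d)),
            class = "distance_profile")
}

#' Estimate biological age from a distance profile
#'
#' Locates the minimum of the distance curve on the 1-year grid. For an
#' interior minimum, the unique parabola through the minimum and its two
#' neighbours is fit and its vertex returned, clamped to the bracketing
#' 1-year interval: `x* = x1 + h (y0 - y2) / (2 (y0 - 2 y1 + y2))`. A
#' minimum at a grid boundary is returned as the boundary age with
#' `at_boundary = TRUE`. Ties on the minimum are broken toward the youngest
#' age and flagged.
#'
#' @param profile A [distance_profile()].
#'
#' @return An object of class `bioage_estimate`: `bio_age` (years,
#'   fractional), `min_distance`, `at_boundary`, `tie`, `profile`.
#' @export
estimate_bioage <- function(profile) {
  stopifnot(inherits(profile, "distance_profile"))
  d <- profile$distances
  a <- profile$age_grid
  if (length(d) < 3L) stop("need at least 3 grid points", call. = FALSE)
  if (diff(range(d)) == 0) {
    stop("ambiguous minimum: distance profile is flat", call. = FALSE)
  }
  mins <- which(d == min(d))
  tie <- length(mins) > 1L
  i <- mins[1L]  # youngest on ties
  if (i == 1L || i == length(d)) {
    return(structure(
      list(bio_age = as.numeric(a[i]), min_distance = d[i],
           at_boundary = TRUE, tie = tie, profile = profile),
      class = "bioage_estimate"))
  }
  y0 <- d[i - 1L]; y1 <- d[i]; y2 <- d[i + 1L]
  h <- a[i] - a[i - 1L]
  denom <- y0 - 2 * y1 + y2
  vertex <- if (denom <= 0) as.numeric(a[i]) else
    a[i] + h * (y0 - y2) / (2 * denom)
  vertex <- min(max(vertex, a[i - 1L]), a[i + 1L])
  structure(
    list(bio_age = vertex, min_distance = y1, at_boundary = FALSE,
         tie = tie, profile = profile),
    class = "bioage_estimate"
  )
}

#' @export
print.bioage_estimate <- function(x, ...) {
  cat(sprintf("biological age: %.2f years%s\n", x$bio_age,
              if (x$at_boundary) " (at grid boundary)" else ""))
  invisible(x)
}

#' Estimate biological age for raw intensities in one call
#'
#' Chains [apply_zscores()], [distance_profile()] and [estimate_bioage()].
#'
#' @param model An `age_curve_model`.
#' @param intensities Full-axis intensity vector (or one-row matrix).
#' @param feature_mz Optional m/z axis for a mismatch check.
#'
#' @return A `bioage_estimate`.
#' @export
estimate_age <- function(model, intensities, feature_mz = NULL) {
  z <- apply_zscores(intensities, model$params, feature_mz = feature_mz)
  estimate_bioage(distance_profile(model, z))
}

#' Change in biological age between two timepoints
#'
#' @param est_t1,est_t2 `bioage_estimate`s from the same model (same grid).
#'
#' @return List with `delta_years` (= t2 - t1) and `delta_days`
#'   (years x 365.25).
#' @export
delta_bioage <- function(est_t1, est_t2) {
  stopifnot(inherits(est_t1, "bioage_estimate"),
            inherits(est_t2, "bioage_estimate"))
  if (!identical(est_t1$profile$age_grid, est_t2$profile$age_grid)) {
    stop("estimates come from different models (age grids differ)",
         call. = FALSE)
  }
  dy <- est_t2$bio_age - est_t1$bio_age
  list(delta_years = dy, delta_days = dy * DAYS_PER_YEAR)
}

#' Metabolic-clock validation against chronological age
#'
#' For each longitudinal pair (two fingerprints of one subject separated by
#' a known calendar gap), the biological-age change is estimated and
#' regressed on the chronological-age change by ordinary least squares (free
#' intercept). With `leave_one_out = TRUE` the age-curve model is retrained
#' for each pair with that subject's samples excluded from the training set,
#' so a subject never influences the curve it is scored against.
#'
#' @param train A training [feature_matrix()] (may contain both sexes).
#' @param followups A [feature_matrix()] of paired samples: exactly two
#'   samples per `subject_id`, ordered by `timepoint`, on the same feature
#'   axis as `train`.
#' @param leave_one_out Retrain per subject, excluding them from `train`.
#' @param alpha,half_window_years,min_nonzero_frac,fdr_method Model settings
#'   (see [train_age_model()]).
#'
#' @return List with `r_squared`, `slope`, `intercept`, and `table` (one row
#'   per pair: `subject_id`, `sex`, `delta_chrono_years`, `delta_bio_years`).
#' @export
validate_clock <- function(train, followups, leave_one_out = TRUE,
                           alpha = 0.01, half_window_years = 3,
                           min_nonzero_frac = 0.15, fdr_method = "bh") {
  stopifnot(inherits(train, "feature_matrix"),
            inherits(followups, "feature_matrix"))
  if (!isTRUE(all.equal(train$feature_mz, followups$feature_mz))) {
    stop("train and follow-up matrices are on different feature axes",
         call. = FALSE)
  }
  subjects <- unique(followups$samples$subject_id)
  counts <- table(followups$samples$subject_id)
  if (any(counts != 2L)) {
    stop("each follow-up subject needs exactly two samples", call. = FALSE)
  }
  if (length(subjects) < 3L) {
    stop("need at least 3 longitudinal pairs", call. = FALSE)
  }

  model_cache <- new.env(parent = emptyenv())
  get_model <- function(sex, exclude_subject) {
    key <- paste(sex, if (leave_one_out) exclude_subject else "", sep = "|")
    if (!is.null(model_cache[[key]])) return(model_cache[[key]])
    fm <- train
    if (leave_one_out) {
      fm <- subset_samples(fm, fm$samples$subject_id != exclude_subject)
    }
    m <- train_age_model(fm, sex, alpha = alpha,
                         half_window_years = half_window_years,
                         min_nonzero_frac = min_nonzero_frac,
                         fdr_method = fdr_method)
    model_cache[[key]] <- m
    m
  }

  rows <- lapply(subjects, function(s) {
    idx <- which(followups$samples$subject_id == s)
    idx <- idx[order(followups$samples$timepoint[idx])]
    meta <- followups$samples[idx, ]
    model <- get_model(meta$sex[1L], s)
    e1 <- estimate_age(model, followups$intensities[idx[1L], ],
                       feature_mz = followups$feature_mz)
    e2 <- estimate_age(model, followups$intensities[idx[2L], ],
                       feature_mz = followups$feature_mz)
    data.frame(subject_id = s, sex = meta$sex[1L],
               delta_chrono_years = meta$age[2L] - meta$age[1L],
               delta_bio_years = delta_bioage(e1, e2)$delta_years,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (stats::var(tab$delta_chrono_years) == 0) {
    stop("undefined fit: chronological-age change is constant across pairs",
         call. = FALSE)
  }
  fit <- stats::lm(delta_bio_years ~ delta_chrono_years, data = tab)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       table = tab)
}

#' Test-retest reliability of repeated biological-age estimates
#'
#' From replicate estimates of the same sample: SD (sample standard
#' deviation), SEM = SD / sqrt(n), MAD = mean |estimate - replicate mean|,
#' a seeded percentile-bootstrap 95% CI for the MAD, and the minimum
#' detectable change ([mdc()]). All reported in days (1 year = 365.25 days).
#'
#' @param replicates A list of `bioage_estimate`s or a numeric vector of
#'   biological ages in years (length >= 2).
#' @param ci_bootstrap_n Bootstrap resamples for the MAD CI.
#' @param seed Seed for the bootstrap (required for reproducibility).
#' @param exclude_outliers Drop replicates with
#'   `|value - median| > 3 * mad(value)` (scaled median absolute deviation)
#'   before computing the statistics; off by default. Exclusions are
#'   reported in the result.
#' @param literal_x2 Passed to [mdc()].
#' @param mad_method `"mean"` (mean absolute deviation from the replicate
#'   mean, default) or `"pairwise"` (mean absolute pairwise difference).
#'
#' @return An object of class `repro_metrics`: `sd_days`, `sem_days`,
#'   `mad_days`, `mad_ci_95` (length-2), `mdc_days`, `n_replicates`,
#'   `excluded` (indices dropped as outliers).
#' @export
repro_metrics <- function(replicates, ci_bootstrap_n = 2000, seed = 1,
                          exclude_outliers = FALSE, literal_x2 = FALSE,
                          mad_method = c("mean", "pairwise")) {
  mad_method <- match.arg(mad_method)
  years <- if (is.numeric(replicates)) replicates else
    vapply(replicates, function(e) {
      stopifnot(inherits(e, "bioage_estimate")); e$bio_age
    }, numeric(1))
  if (length(years) < 2L) {
    stop("need at least 2 replicate estimates", call. = FALSE)
  }
  excluded <- integer(0)
  if (exclude_outliers) {
    s <- stats::mad(years)  # scaled MAD, consistent with sd under normality
    if (s > 0) {
      excluded <- which(abs(years - stats::median(years)) > 3 * s)
      if (length(excluded) && length(years) - length(excluded) >= 2L) {
        years <- years[-excluded]
      } else {
        excluded <- integer(0)
      }
    }
  }
  days <- years * DAYS_PER_YEAR
  n <- length(days)
  sd_days <- stats::sd(days)
  sem_days <- sd_days / sqrt(n)
  mad_fun <- switch(mad_method,
                    mean = function(x) mean(abs(x - mean(x))),
                    pairwise = function(x) mean(abs(outer(x, x, `-`))[
                      upper.tri(diag(length(x)))]))
  mad_days <- mad_fun(days)
  ci <- with_local_seed(seed, {
    boots <- vapply(seq_len(ci_bootstrap_n), function(i) {
      mad_fun(sample(days, n, replace = TRUE))
    }, numeric(1))
    stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  })
  structure(
    list(sd_days = sd_days, sem_days = sem_days, mad_days = mad_days,
         mad_ci_95 = ci, mdc_days = mdc(sem_days, literal_x2 = literal_x2),
         n_replicates = n, excluded = excluded),
    class = "repro_metrics"
  )
}

#' @export
print.repro_metrics <- function(x, ...) {
  cat(sprintf(
    "repro_metrics (n = %d): SD %.1f d, SEM %.1f d, MAD %.1f d (95%% CI %.1f-%.1f), MDC %.1f d\n",
    x$n_replicates, x$sd_days, x$sem_days, x$mad_days,
    x$mad_ci_95[1], x$mad_ci_95[2], x$mdc_days))
  invisible(x)
}

#' Minimum detectable change at 95% confidence
#'
#' `MDC = 1.96 * sqrt(2) * SEM`, the standard test-retest formula (the
#' sqrt(2) reflects that a change is the difference of two measurements).
#' `literal_x2 = TRUE` uses `1.96 * 2 * SEM` instead.
#'
#' @param sem_days Standard error of measurement in days (>= 0).
#' @param confidence_constant Normal quantile for the confidence level
#'   (1.96 for 95%).
#' @param literal_x2 Use the factor 2 instead of sqrt(2).
#'
#' @return MDC in days.
#' @export
#' @examples
#' mdc(10) # 27.72
mdc <- function(sem_days, confidence_constant = 1.96, literal_x2 = FALSE) {
  if (sem_days < 0) stop("'sem_days' must be non-negative", call. = FALSE)
  confidence_constant * (if (literal_x2) 2 else sqrt(2)) * sem_days
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
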