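#' Configuration for synthetic fingerprint cohorts
#'
#' Describes a cohort of adult subjects with thousands of mass-spectral
#' features, a fraction of which follow age-related trajectories: monotone
#' (linear in age) or "wave" (a logistic transition centred in mid-life,
#' at 50 years in men and 47 in women by default). Intensities are
#' log-normal: per-feature baseline log-intensity, plus the trajectory
#' signal, plus Gaussian noise on the log scale, exponentiated; dropout
#' then zeroes entries at random (zero = peak absent).
#'
#' `effect_size` is the z-score span of an age trajectory at a reference
#' noise level: the amplitude `A` (log-intensity units) of a linear
#' trajectory is calibrated so that, after standardizing over a cohort with
#' uniform ages and log-noise `ref_noise_sd`, the trajectory spans
#' `effect_size` z-units end to end:
#' `A = ref_noise_sd / sqrt(1 / effect_size^2 - 1/12)`. The amplitude is
#' therefore independent of the cohort's actual `noise_sd`, so lowering
#' `noise_sd` below the reference sharpens the standardized signal (the
#' realized span saturates at `sqrt(12) ~ 3.46` z-units as noise vanishes,
#' which is why `effect_size` must stay below that). Dropout adds further
#' non-age variance and shrinks the realized span somewhat below nominal.
#'
#' @param n_subjects Number of subjects (one sample each).
#' @param age_range Integer age span, default 18-81 years.
#' @param sex_ratio Proportion of males.
#' @param n_features Number of spectral features (default 3000).
#' @param frac_age_assoc Fraction of features with an age trajectory
#'   (default 0.3).
#' @param trajectory_mix Named proportions for `linear` and `wave`
#'   trajectories among age-associated features.
#' @param wave_age Named change-ages of the wave trajectory per sex
#'   (years).
#' @param wave_scale Logistic width of the wave (years).
#' @param effect_size Nominal z-score span of an age trajectory across the
#'   age range at the reference noise level (must be below `sqrt(12)`).
#' @param ref_noise_sd Reference log-noise level at which `effect_size`
#'   z-units are realized (default 0.3, a typical ~30% technical CV of
#'   direct-infusion peak intensities).
#' @param noise_sd Per-measurement (technical) log-intensity noise sd.
#' @param subject_sd Between-subject log-intensity sd at fixed age: each
#'   subject carries a persistent per-feature fingerprint offset, constant
#'   across timepoints and replicates (default 0.1). This is why an
#'   individual's distance profile has a floor well above zero, and why the
#'   offset cancels when differencing two estimates of the same subject.
#' @param dropout_prob Probability an entry is zeroed (missing peak).
#' @param dropout_intensity_dep If `TRUE`, low-intensity entries drop out
#'   preferentially (probability scaled by the within-feature intensity
#'   rank); mean rate stays `dropout_prob`.
#' @param replicate_noise_sd Log-intensity noise for technical replicates.
#' @param base_log_mean,base_log_sd Baseline log-intensity distribution
#'   across features.
#' @param mz_range m/z span over which synthetic feature masses are drawn.
#' @param seed Mandatory integer seed.
#'
#' @return An object of class `sim_config` (validated named list).
#' @export
sim_config <- function(n_subjects = 190, age_range = c(18L, 81L),
                       sex_ratio = 0.5, n_features = 3000,
                       frac_age_assoc = 0.3,
                       trajectory_mix = c(linear = 0.7, wave = 0.3),
                       wave_age = c(male = 50, female = 47),
                       wave_scale = 3,
                       effect_size = 3, ref_noise_sd = 0.3,
                       noise_sd = 0.3, subject_sd = 0.1, dropout_prob = 0.1,
                       dropout_intensity_dep = FALSE,
                       replicate_noise_sd = 0.1,
                       base_log_mean = log(1e4), base_log_sd = 1,
                       mz_range = c(100, 1000), seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("'seed' is mandatory for any stochastic call", call. = FALSE)
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              age_range = as.integer(age_range), sex_ratio = sex_ratio,
              n_features = as.integer(n_features),
              frac_age_assoc = frac_age_assoc,
              trajectory_mix = trajectory_mix / sum(trajectory_mix),
              wave_age = wave_age, wave_scale = wave_scale,
              effect_size = effect_size, ref_noise_sd = ref_noise_sd,
              noise_sd = noise_sd, subject_sd = subject_sd,
              dropout_prob = dropout_prob,
              dropout_intensity_dep = isTRUE(dropout_intensity_dep),
              replicate_noise_sd = replicate_noise_sd,
              base_log_mean = base_log_mean, base_log_sd = base_log_sd,
              mz_range = as.numeric(mz_range), seed = as.integer(seed))
  with(cfg, {
    if (n_subjects < 1L || n_features < 1L) {
      stop("n_subjects and n_features must be >= 1", call. = FALSE)
    }
    if (age_range[1L] < 0L || age_range[2L] <= age_range[1L]) {
      stop("invalid age_range", call. = FALSE)
    }
    probs <- c(sex_ratio, frac_age_assoc, dropout_prob)
    if (any(probs < 0 | probs > 1)) {
      stop("sex_ratio, frac_age_assoc, dropout_prob must be in [0, 1]",
           call. = FALSE)
    }
    if (noise_sd < 0 || replicate_noise_sd < 0 || effect_size < 0 ||
        subject_sd < 0 || ref_noise_sd <= 0) {
      stop("noise and effect sizes must be non-negative and ref_noise_sd positive",
           call. = FALSE)
    }
    if (effect_size >= sqrt(12)) {
      stop("effect_size must be below sqrt(12) ~ 3.46 z-units ",
           "(the span of a noiseless standardized linear trajectory)",
           call. = FALSE)
    }
    if (!setequal(names(trajectory_mix), c("linear", "wave"))) {
      stop("trajectory_mix needs 'linear' and 'wave' entries", call. = FALSE)
    }
  })
  structure(cfg, class = "sim_config")
}

# trajectory value in [0, 1] at `age` (vectorized), given type and sex
sim_trajectory_g <- function(age, type, sex, cfg) {
  lo <- cfg$age_range[1L]; hi <- cfg$age_range[2L]
  if (type == "linear") {
    (age - lo) / (hi - lo)
  } else {
    centre <- unname(cfg$wave_age[sex])
    stats::plogis((age - centre) / cfg$wave_scale)
  }
}

# trajectory amplitude (log-intensity units) realizing the nominal z-span
# at the reference noise level; independent of the cohort's actual noise_sd
sim_amplitude <- function(cfg) {
  if (cfg$effect_size == 0) return(0)
  cfg$ref_noise_sd / sqrt(1 / cfg$effect_size^2 - 1 / 12)
}

# noiseless log-intensity matrix for given ages/sexes under feature truth;
# subject_rows (indices into truth$subjects) add the subjects' persistent
# fingerprint offsets
sim_signal_log <- function(ages, sexes, truth, cfg, subject_rows = NULL) {
  n <- length(ages); p <- nrow(truth$features)
  out <- matrix(rep(truth$features$base_log, each = n), n, p)
  if (!is.null(subject_rows) && !is.null(truth$subject_offset)) {
    out <- out + truth$subject_offset[subject_rows, , drop = FALSE]
  }
  amp <- sim_amplitude(cfg)
  g_linear <- sim_trajectory_g(ages, "linear", sexes, cfg)
  centre <- unname(cfg$wave_age[sexes])
  g_wave <- stats::plogis((ages - centre) / cfg$wave_scale)
  for (type in c("linear", "wave")) {
    idx <- which(truth$features$age_associated &
                   truth$features$trajectory == type)
    if (!length(idx)) next
    g <- if (type == "linear") g_linear else g_wave
    out[, idx] <- out[, idx] +
      g %o% (amp * truth$features$direction_num[idx])
  }
  out
}

# apply noise + dropout to a log-signal matrix and exponentiate
sim_observe <- function(log_signal, noise_sd, cfg) {
  n <- nrow(log_signal); p <- ncol(log_signal)
  x <- log_signal
  if (noise_sd > 0) x <- x + matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  intens <- exp(x)
  if (cfg$dropout_prob > 0) {
    if (cfg$dropout_intensity_dep) {
      # rank-scaled: weakest entry of a feature drops ~2x the mean rate
      r <- apply(intens, 2L, rank, ties.method = "average")
      prob <- cfg$dropout_prob * 2 * (1 - (r - 0.5) / n)
      drop <- matrix(stats::runif(n * p), n, p) < prob
    } else {
      drop <- matrix(stats::runif(n * p), n, p) < cfg$dropout_prob
    }
    intens[drop] <- 0
  }
  intens
}

#' Simulate a cross-sectional fingerprint cohort
#'
#' Draws subjects with integer ages uniform over `cfg$age_range`, assigns
#' sex by `cfg$sex_ratio`, and generates a samples x features intensity
#' matrix under the log-normal trajectory model of [sim_config()].
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#'
#' @return List with `matrix` (a [feature_matrix()]) and `truth` (class
#'   `sim_truth`): `subjects` (`subject_id`, `true_age`, `sex`) and
#'   `features` (`feature_mz`, `age_associated`, `trajectory`, `direction`,
#'   `base_log`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    n <- cfg$n_subjects; p <- cfg$n_features
    # designed recruitment: within each sex, integer ages cover the range
    # evenly (shuffled round-robin), as in a cohort assembled to build
    # per-sex age curves
    n_male <- round(cfg$sex_ratio * n)
    sexes <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    span <- seq(cfg$age_range[1L], cfg$age_range[2L])
    ages <- integer(n)
    for (sx in c("male", "female")) {
      idx <- which(sexes == sx)
      if (length(idx)) ages[idx] <- sample(rep_len(span, length(idx)))
    }
    feature_mz <- sort(stats::runif(p, cfg$mz_range[1L], cfg$mz_range[2L]))
    n_assoc <- round(cfg$frac_age_assoc * p)
    assoc <- sort(sample.int(p, n_assoc))
    trajectory <- rep(NA_character_, p)
    n_wave <- round(cfg$trajectory_mix[["wave"]] * n_assoc)
    wave_idx <- if (n_wave > 0) sample(assoc, n_wave) else integer(0)
    trajectory[assoc] <- "linear"
    trajectory[wave_idx] <- "wave"
    direction_num <- rep(0, p)
    direction_num[assoc] <- sample(c(-1, 1), n_assoc, replace = TRUE)
    features <- data.frame(
      feature_mz = feature_mz,
      age_associated = seq_len(p) %in% assoc,
      trajectory = trajectory,
      direction = c("negative", "none", "positive")[direction_num + 2],
      direction_num = direction_num,
      base_log = stats::rnorm(p, cfg$base_log_mean, cfg$base_log_sd),
      stringsAsFactors = FALSE
    )
    truth <- structure(
      list(subjects = data.frame(subject_id = sprintf("SUBJ%04d", seq_len(n)),
                                 true_age = ages, sex = sexes,
                                 stringsAsFactors = FALSE),
           features = features,
           subject_offset = matrix(stats::rnorm(n * p, 0, cfg$subject_sd),
                                   n, p),
           cfg = cfg),
      class = "sim_truth")
    intens <- sim_observe(sim_signal_log(ages, sexes, truth, cfg,
                                         subject_rows = seq_len(n)),
                          cfg$noise_sd, cfg)
    samples <- data.frame(sample_id = sprintf("SUBJ%04d_t0", seq_len(n)),
                          subject_id = truth$subjects$subject_id,
                          age = ages, sex = sexes, sample_type = "plasma",
                          timepoint = 0, fasting = TRUE,
                          stringsAsFactors = FALSE)
    list(matrix = feature_matrix(intens, feature_mz, samples), truth = truth)
  })
}

#' Simulate longitudinal follow-up samples
#'
#' Re-samples chosen subjects of a simulated cohort after calendar gaps,
#' with chronological age advanced by `gap * aging_rate` and fresh noise and
#' dropout. Each selected subject yields one pair: a fresh baseline sample
#' at the original age and a follow-up after their gap (gaps are recycled
#' over subjects).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param subjects Subject ids to follow; default all.
#' @param gaps_months Calendar gaps in months, recycled over subjects
#'   (default `c(3, 6, 12, 18)`).
#' @param aging_rate Biological-aging years per calendar year (default 1).
#' @param seed Integer seed.
#'
#' @return List with `matrix` (a [feature_matrix()] holding two samples per
#'   subject, timepoints 0 and the gap in years) and `pairs` (`subject_id`,
#'   `gap_months`, `delta_age_years` = true biological-age change).
#' @export
simulate_followups <- function(cohort, subjects = NULL,
                               gaps_months = c(3, 6, 12, 18),
                               aging_rate = 1.0, seed) {
  stopifnot(inherits(cohort$truth, "sim_truth"))
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (any(gaps_months <= 0)) stop("gaps must be positive", call. = FALSE)
  cfg <- cohort$truth$cfg
  subj <- cohort$truth$subjects
  if (is.null(subjects)) subjects <- subj$subject_id
  if (!all(subjects %in% subj$subject_id)) {
    stop("unknown subject id(s)", call. = FALSE)
  }
  with_local_seed(seed, {
    ridx <- match(subjects, subj$subject_id)
    rows <- subj[ridx, ]
    gaps <- rep_len(gaps_months, nrow(rows))
    delta <- gaps / 12 * aging_rate
    ages <- c(rows$true_age, rows$true_age + delta)
    sexes <- rep(rows$sex, 2L)
    intens <- sim_observe(sim_signal_log(ages, sexes, cohort$truth, cfg,
                                         subject_rows = rep(ridx, 2L)),
                          cfg$noise_sd, cfg)
    k <- nrow(rows)
    samples <- data.frame(
      sample_id = c(sprintf("%s_fu0", rows$subject_id),
                    sprintf("%s_fu1", rows$subject_id)),
      subject_id = rep(rows$subject_id, 2L),
      age = ages, sex = sexes, sample_type = "plasma",
      timepoint = c(rep(0, k), gaps / 12),
      fasting = TRUE, stringsAsFactors = FALSE)
    list(matrix = feature_matrix(intens, cohort$truth$features$feature_mz,
                                 samples),
         pairs = data.frame(subject_id = rows$subject_id, gap_months = gaps,
                            delta_age_years = delta,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate technical replicates of one sample
#'
#' Repeated acquisitions of the same sample: the noiseless signal at the
#' subject's age plus fresh multiplicative log-normal noise per replicate —
#' no age shift and no dropout re-draw, so `replicate_noise_sd = 0` yields
#' byte-identical replicates.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param subject_id Subject to replicate; default the first.
#' @param n Number of replicates (>= 2; default 10).
#' @param replicate_noise_sd Log-intensity noise sd; default from the
#'   cohort's config.
#' @param seed Integer seed.
#'
#' @return A [feature_matrix()] of `n` replicate rows.
#' @export
simulate_replicates <- function(cohort, subject_id = NULL, n = 10,
                                replicate_noise_sd = NULL, seed) {
  stopifnot(inherits(cohort$truth, "sim_truth"))
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (n < 2L) stop("need at least 2 replicates", call. = FALSE)
  cfg <- cohort$truth$cfg
  if (is.null(replicate_noise_sd)) replicate_noise_sd <- cfg$replicate_noise_sd
  subj <- cohort$truth$subjects
  if (is.null(subject_id)) subject_id <- subj$subject_id[1L]
  row <- subj[subj$subject_id == subject_id, ]
  if (!nrow(row)) stop("unknown subject id", call. = FALSE)
  cfg_rep <- cfg
  cfg_rep$dropout_prob <- 0
  ridx <- which(subj$subject_id == subject_id)
  with_local_seed(seed, {
    ages <- rep(row$true_age, n)
    sexes <- rep(row$sex, n)
    intens <- sim_observe(sim_signal_log(ages, sexes, cohort$truth, cfg,
                                         subject_rows = rep(ridx, n)),
                          replicate_noise_sd, cfg_rep)
    samples <- data.frame(sample_id = sprintf("%s_rep%02d", subject_id,
                                              seq_len(n)),
                          subject_id = subject_id, age = ages, sex = sexes,
                          sample_type = "plasma", timepoint = 0,
                          fasting = TRUE, stringsAsFactors = FALSE)
    feature_matrix(intens, cohort$truth$features$feature_mz, samples)
  })
}
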