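# shared fixture builders (everything generated in code)

toy_meta <- function(id = "S1", age = 30, sex = "male") {
  sample_meta(id, age = age, sex = sex)
}

# peak list with the internal standard present, optionally offset in ppm
toy_peaklist <- function(std_ppm_offset = 0, extra_mz = c(150.05, 300.1),
                         extra_intensity = c(500, 800), meta = NULL) {
  std <- 423.169 * (1 + std_ppm_offset * 1e-6)
  peaklist(c(extra_mz, std), c(extra_intensity, 1e5), meta = meta)
}

# small feature matrix with metadata; intensities supplied by column
toy_feature_matrix <- function(intensities, ages,
                               sexes = rep("male", length(ages)),
                               feature_mz = NULL) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  if (is.null(feature_mz)) feature_mz <- 100 + seq_len(ncol(intensities))
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    subject_id = sprintf("S%03d", seq_len(n)),
    age = ages, sex = sexes, sample_type = "plasma",
    timepoint = 0, fasting = TRUE, stringsAsFactors = FALSE)
  feature_matrix(intensities, feature_mz, samples)
}

# deterministic distance profile object
toy_profile <- function(distances, ages = seq(30, length.out = length(distances))) {
  structure(list(age_grid = as.integer(ages), distances = distances),
            class = "distance_profile")
}

# closed-form parabola vertex through (x1-h, y0), (x1, y1), (x1+h, y2):
# independent oracle for estimate_bioage
parabola_vertex <- function(x1, h, y0, y1, y2) {
  x1 + h * (y0 - y2) / (2 * (y0 - 2 * y1 + y2))
}
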