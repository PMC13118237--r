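#' Construct a feature matrix
#'
#' Samples x features intensity matrix on a common aligned m/z axis; a zero
#' entry means the peak was absent from that sample's spectrum. Per-sample
#' metadata travel with the matrix.
#'
#' @param intensities Numeric matrix, samples in rows, features in columns,
#'   non-negative; 0 encodes a missing peak.
#' @param feature_mz Strictly increasing numeric vector of consensus feature
#'   m/z values (Da), one per column.
#' @param samples `data.frame` with one row per sample and columns
#'   `sample_id`, `subject_id`, `age`, `sex`, `sample_type`, `timepoint`,
#'   `fasting`. `sample_id` must be unique.
#'
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(intensities, feature_mz, samples) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  feature_mz <- as.numeric(feature_mz)
  if (ncol(intensities) != length(feature_mz)) {
    stop("ncol(intensities) must equal length(feature_mz)", call. = FALSE)
  }
  if (length(feature_mz) > 1 && any(diff(feature_mz) <= 0)) {
    stop("'feature_mz' must be strictly increasing", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  required <- c("sample_id", "subject_id", "age", "sex", "sample_type",
                "timepoint", "fasting")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample metadata missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(samples) != nrow(intensities)) {
    stop("one metadata row per sample required", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  samples <- as.data.frame(samples)[, required]
  samples$sample_id <- as.character(samples$sample_id)
  samples$subject_id <- as.character(samples$subject_id)
  samples$age <- as.numeric(samples$age)
  rownames(intensities) <- samples$sample_id
  colnames(intensities) <- format_feature_mz(feature_mz)
  structure(
    list(intensities = intensities, feature_mz = feature_mz, samples = samples),
    class = "feature_matrix"
  )
}

# feature column labels: m/z to 4 decimals
format_feature_mz <- function(mz) sprintf("%.4f", mz)

#' @export
print.feature_matrix <- function(x, ...) {
  nz <- mean(x$intensities > 0) * 100
  cat(sprintf("feature_matrix: %d samples x %d features (%.1f%% non-zero)\n",
              nrow(x$intensities), ncol(x$intensities), nz))
  cat(sprintf("  m/z %.4f-%.4f; ages %.0f-%.0f y; %d male / %d female\n",
              min(x$feature_mz), max(x$feature_mz),
              min(x$samples$age), max(x$samples$age),
              sum(x$samples$sex == "male"), sum(x$samples$sex == "female")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensities)

#' Subset a feature matrix by sample
#'
#' @param fm A [feature_matrix()].
#' @param i Row (sample) index, logical or integer.
#' @return A [feature_matrix()] with the selected samples.
#' @export
subset_samples <- function(fm, i) {
  stopifnot(inherits(fm, "feature_matrix"))
  feature_matrix(fm$intensities[i, , drop = FALSE], fm$feature_mz,
                 fm$samples[i, , drop = FALSE])
}

#' Write a feature matrix to CSV
#'
#' Layout: metadata columns (`sample_id`, `subject_id`, `age`, `sex`,
#' `sample_type`, `timepoint`, `fasting`) followed by one column per
#' feature, named by its m/z to 4 decimals. Zeros are written as zeros;
#' intensities keep full double precision.
#'
#' @param fm A [feature_matrix()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  dt <- data.table::as.data.table(fm$samples)
  mat <- data.table::as.data.table(fm$intensities)
  data.table::setnames(mat, format_feature_mz(fm$feature_mz))
  data.table::fwrite(cbind(dt, mat), path)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Inverse of [write_feature_matrix()]: requires the full metadata header
#' and at least one feature column.
#'
#' @param path CSV path produced by [write_feature_matrix()] (or following
#'   the same layout).
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, data.table = FALSE)
  meta_cols <- c("sample_id", "subject_id", "age", "sex", "sample_type",
                 "timepoint", "fasting")
  missing_cols <- setdiff(meta_cols, names(dt))
  if (length(missing_cols)) {
    stop("feature-matrix file missing metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  feat_cols <- setdiff(names(dt), meta_cols)
  if (!length(feat_cols)) stop("no feature columns found in ", path, call. = FALSE)
  feature_mz <- suppressWarnings(as.numeric(feat_cols))
  if (anyNA(feature_mz)) {
    stop("non-numeric feature column name(s) in ", path, call. = FALSE)
  }
  feature_matrix(as.matrix(dt[, feat_cols, drop = FALSE]), feature_mz,
                 dt[, meta_cols])
}
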