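#' Construct a sample metadata record
#'
#' Metadata carried by every fingerprint: who was sampled, their
#' chronological age, sex, the sample matrix (venous plasma or dried blood
#' spot), the timepoint, and whether the subject was fasted at collection.
#'
#' @param subject_id Opaque subject identifier (coerced to character).
#' @param age Chronological age in years (>= 0, fractional allowed).
#' @param sex `"male"` or `"female"`.
#' @param sample_type `"plasma"` or `"DBS"`.
#' @param timepoint Calendar date or numeric study-day offset (default 0).
#' @param fasting Logical fasting flag at collection (default `TRUE`).
#'
#' @return An object of class `sample_meta` (a named list).
#' @export
#' @examples
#' sample_meta("S01", age = 36, sex = "male")
sample_meta <- function(subject_id, age, sex,
                        sample_type = c("plasma", "DBS"),
                        timepoint = 0, fasting = TRUE) {
  sex <- match.arg(sex, c("male", "female"))
  sample_type <- match.arg(sample_type)
  age <- as.numeric(age)
  if (is.na(age) || age < 0) {
    stop("'age' must be a non-negative number of years", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), age = age, sex = sex,
         sample_type = sample_type, timepoint = timepoint,
         fasting = isTRUE(fasting)),
    class = "sample_meta"
  )
}

#' Construct a peak list
#'
#' One direct-infusion mass spectrum reduced to centroided (m/z, intensity)
#' pairs. m/z values are stored strictly increasing; duplicate m/z entries
#' are merged by summing their intensities.
#'
#' @param mz Numeric vector of mass-to-charge values (Da, positive).
#' @param intensity Numeric vector of non-negative intensities, same length.
#' @param meta Optional [sample_meta()] record.
#' @param calibration_scale Multiplicative m/z scale already applied
#'   (bookkeeping for [recalibrate()]; default `NA` = never calibrated).
#'
#' @return An object of class `peaklist` with elements `mz`, `intensity`,
#'   `meta`, `calibration_scale`.
#' @export
#' @examples
#' peaklist(c(100, 200), c(5, 7))
peaklist <- function(mz, intensity, meta = NULL, calibration_scale = NA_real_) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("'mz' and 'intensity' must have the same length", call. = FALSE)
  }
  if (anyNA(mz) || anyNA(intensity)) {
    stop("peak list contains missing values", call. = FALSE)
  }
  if (length(mz) && any(mz <= 0)) {
    stop("all m/z values must be positive", call. = FALSE)
  }
  if (length(intensity) && any(intensity < 0)) {
    stop("all intensities must be non-negative", call. = FALSE)
  }
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  if (!is.null(meta) && !inherits(meta, "sample_meta")) {
    stop("'meta' must be a sample_meta object", call. = FALSE)
  }
  structure(
    list(mz = mz, intensity = intensity, meta = meta,
         calibration_scale = calibration_scale),
    class = "peaklist"
  )
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("peaklist: %d peaks, m/z %.4f-%.4f\n",
              length(x$mz),
              if (length(x$mz)) min(x$mz) else NA, if (length(x$mz)) max(x$mz) else NA))
  if (!is.null(x$meta)) {
    cat(sprintf("  subject %s, age %.1f y, %s, %s\n", x$meta$subject_id,
                x$meta$age, x$meta$sex, x$meta$sample_type))
  }
  if (!is.na(x$calibration_scale)) {
    cat(sprintf("  recalibrated (scale %.8f)\n", x$calibration_scale))
  }
  invisible(x)
}

#' @export
length.peaklist <- function(x) length(x$mz)

#' Read a peak list from CSV/TSV or centroided mzML
#'
#' CSV/TSV files must contain two numeric columns, m/z then intensity
#' (header `mz,intensity` accepted and skipped). Rows are sorted by m/z and
#' duplicate m/z rows merged by intensity sum. mzML reading (first centroided
#' spectrum) requires the `mzR` package.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"` or `"mzml"`; default guessed from the
#'   file extension.
#' @param meta Optional [sample_meta()] attached to the result.
#'
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, format = c("auto", "csv", "tsv", "mzml"),
                          meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", mzml = "mzml", "csv")
  }
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the 'mzR' package", call. = FALSE)
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h), add = TRUE)
    pk <- mzR::peaks(h, 1L)
    return(peaklist(pk[, 1L], pk[, 2L], meta = meta))
  }
  sep <- if (format == "tsv") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty peak-list file: ", path, call. = FALSE)
  start <- 1L
  first <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  if (suppressWarnings(anyNA(as.numeric(first)))) start <- 2L  # header row
  if (start > length(lines)) {
    stop("peak-list file has a header but no data rows: ", path, call. = FALSE)
  }
  n <- length(lines) - start + 1L
  mz <- numeric(n); intensity <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[start + i - 1L], sep, fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      stop(sprintf("malformed peak-list row at line %d of %s: '%s'",
                   start + i - 1L, path, lines[start + i - 1L]), call. = FALSE)
    }
    if (vals[2L] < 0) {
      stop(sprintf("negative intensity at line %d of %s",
                   start + i - 1L, path), call. = FALSE)
    }
    mz[i] <- vals[1L]; intensity[i] <- vals[2L]
  }
  peaklist(mz, intensity, meta = meta)
}

#' Write a peak list to CSV
#'
#' @param pl A [peaklist()].
#' @param path Output path; a `mz,intensity` header is written.
#' @return Invisibly, `path`.
#' @export
write_peaklist <- function(pl, path) {
  stopifnot(inherits(pl, "peaklist"))
  utils::write.csv(data.frame(mz = pl$mz, intensity = pl$intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recalibrate m/z values against an internal standard
#'
#' Locates the most intense peak within `tol_ppm` of the internal-standard
#' mass (losartan, m/z 423.169, by default) and rescales every m/z by a
#' single multiplicative factor so that this peak lands exactly on the
#' reference mass. Ties on intensity are broken by the smallest absolute
#' ppm error. One internal standard supports one degree of freedom, hence a
#' scale, not an affine map.
#'
#' @param pl A non-empty [peaklist()].
#' @param ref_mz Reference m/z of the internal standard (Da).
#' @param tol_ppm Search tolerance around `ref_mz` in parts per million.
#'
#' @return The recalibrated [peaklist()]; `calibration_scale` records the
#'   factor applied. Idempotent: a second pass finds the standard exactly on
#'   `ref_mz` and applies scale 1.
#' @export
recalibrate <- function(pl, ref_mz = 423.169, tol_ppm = 20) {
  stopifnot(inherits(pl, "peaklist"))
  if (!length(pl$mz)) stop("cannot recalibrate an empty peak list", call. = FALSE)
  ppm_err <- (pl$mz - ref_mz) / ref_mz * 1e6
  cand <- which(abs(ppm_err) <= tol_ppm)
  if (!length(cand)) {
    stop(sprintf(
      "calibration error: no peak within %g ppm of m/z %.4f (nearest is %.1f ppm away)",
      tol_ppm, ref_mz, min(abs(ppm_err))), call. = FALSE)
  }
  best <- cand[order(-pl$intensity[cand], abs(ppm_err[cand]))][1L]
  scale <- ref_mz / pl$mz[best]
  out <- peaklist(pl$mz * scale, pl$intensity, meta = pl$meta,
                  calibration_scale = scale)
  # guard against float dust so the standard sits exactly on ref_mz
  out$mz[which.min(abs(out$mz - ref_mz))] <- ref_mz
  out
}

#' Apply relative and absolute intensity thresholds
#'
#' Keeps peaks whose intensity is at least
#' `max(rel_pct / 100 * max(intensity), abs_min)`. Defaults reproduce the
#' standard spectrum-processing settings (relative 0.01%, absolute 100).
#'
#' @param pl A non-empty [peaklist()].
#' @param rel_pct Relative threshold as a percentage of the base peak.
#' @param abs_min Absolute intensity floor.
#'
#' @return The filtered [peaklist()] (possibly empty).
#' @export
apply_intensity_thresholds <- function(pl, rel_pct = 0.01, abs_min = 100) {
  stopifnot(inherits(pl, "peaklist"))
  if (!length(pl$mz)) stop("empty peak list", call. = FALSE)
  cutoff <- max(rel_pct / 100 * max(pl$intensity), abs_min)
  keep <- pl$intensity >= cutoff
  peaklist(pl$mz[keep], pl$intensity[keep], meta = pl$meta,
           calibration_scale = pl$calibration_scale)
}
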