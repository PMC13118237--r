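#' Align peak lists onto a common feature axis
#'
#' Pools the peaks of all spectra, sorted by m/z, and clusters them greedily:
#' walking up the m/z axis, a peak joins the current cluster while its ppm
#' distance to the running centroid (mean m/z of members so far) is within
#' `tol_ppm`, otherwise it opens a new cluster. Optionally, adjacent clusters
#' whose centroids lie within `2 * tol_ppm` and whose across-sample intensity
#' patterns correlate above `corr_threshold` are then merged iteratively
#' until no merge applies — a deterministic surrogate for
#' correlation-pattern-based alignment of direct-infusion spectra. Each final
#' cluster becomes one feature; a sample contributes the sum of its peak
#' intensities falling in the cluster, and 0 where it has none.
#'
#' @param spectra List of recalibrated [peaklist()] objects (length >= 2).
#' @param tol_ppm Clustering tolerance in parts per million.
#' @param corr_merge Run the correlation-gated merge refinement?
#' @param corr_threshold Pearson correlation (across samples) above which
#'   adjacent close clusters are merged.
#' @param require_calibrated Refuse spectra never passed through
#'   [recalibrate()]? Default `TRUE`.
#' @param weighted_centroid Use intensity-weighted instead of unweighted
#'   mean m/z for cluster centroids.
#'
#' @return A [feature_matrix()]; total intensity is conserved, i.e.
#'   `sum(result$intensities)` equals the summed intensity of all inputs.
#' @export
align_spectra <- function(spectra, tol_ppm = 10, corr_merge = TRUE,
                          corr_threshold = 0.8, require_calibrated = TRUE,
                          weighted_centroid = FALSE) {
  if (!is.list(spectra) || length(spectra) < 2L) {
    stop("'spectra' must be a list of at least two peaklist objects",
         call. = FALSE)
  }
  if (!all(vapply(spectra, inherits, logical(1), "peaklist"))) {
    stop("every element of 'spectra' must be a peaklist", call. = FALSE)
  }
  if (require_calibrated &&
      any(vapply(spectra, function(p) is.na(p$calibration_scale), logical(1)))) {
    stop("spectra must be recalibrated before alignment ",
         "(or set require_calibrated = FALSE)", call. = FALSE)
  }
  if (any(vapply(spectra, function(p) length(p$mz) == 0L, logical(1)))) {
    stop("empty peak list in input", call. = FALSE)
  }

  n <- length(spectra)
  mz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
  intensity <- unlist(lapply(spectra, `[[`, "intensity"), use.names = FALSE)
  sample_idx <- rep.int(seq_len(n),
                        vapply(spectra, function(p) length(p$mz), integer(1)))
  o <- order(mz, sample_idx)
  mz <- mz[o]; intensity <- intensity[o]; sample_idx <- sample_idx[o]

  cluster <- greedy_ppm_clusters(mz, intensity, tol_ppm, weighted_centroid)

  # cluster -> feature bookkeeping as a list of member index vectors
  members <- split(seq_along(mz), cluster)
  if (corr_merge && length(members) > 1L) {
    repeat {
      cent <- cluster_centroids(members, mz, intensity, weighted_centroid)
      inten <- cluster_sample_sums(members, intensity, sample_idx, n)
      merged <- FALSE
      for (k in seq_len(length(members) - 1L)) {
        gap_ppm <- (cent[k + 1L] - cent[k]) /
          ((cent[k] + cent[k + 1L]) / 2) * 1e6
        if (gap_ppm >= 2 * tol_ppm) next
        a <- inten[, k]; b <- inten[, k + 1L]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) next
        if (stats::cor(a, b) > corr_threshold) {
          members[[k]] <- c(members[[k]], members[[k + 1L]])
          members[[k + 1L]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }

  cent <- cluster_centroids(members, mz, intensity, weighted_centroid)
  mat <- cluster_sample_sums(members, intensity, sample_idx, n)
  o <- order(cent)
  cent <- cent[o]; mat <- mat[, o, drop = FALSE]
  if (any(diff(cent) <= 0)) {
    # degenerate duplicate centroids: collapse (conserves intensity)
    grp <- cumsum(c(TRUE, diff(cent) > 0))
    mat <- t(rowsum(t(mat), grp))
    cent <- as.numeric(tapply(cent, grp, `[`, 1L))
  }

  samples <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- spectra[[i]]$meta
    if (is.null(m)) {
      data.frame(sample_id = sprintf("S%03d", i), subject_id = sprintf("S%03d", i),
                 age = NA_real_, sex = NA_character_, sample_type = NA_character_,
                 timepoint = NA, fasting = NA, stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = if (!is.null(m$sample_id)) m$sample_id else
                   sprintf("%s_t%s", m$subject_id, format(m$timepoint)),
                 subject_id = m$subject_id, age = m$age, sex = m$sex,
                 sample_type = m$sample_type, timepoint = m$timepoint,
                 fasting = m$fasting, stringsAsFactors = FALSE)
    }
  }))
  if (anyDuplicated(samples$sample_id)) {
    samples$sample_id <- make.unique(samples$sample_id, sep = "_r")
  }
  feature_matrix(mat, cent, samples)
}

# Greedy single-pass clustering of sorted m/z values against the running
# centroid; returns an integer cluster id per peak.
greedy_ppm_clusters <- function(mz, intensity, tol_ppm, weighted) {
  m <- length(mz)
  cluster <- integer(m)
  k <- 0L
  cent <- 0; csum <- 0; wsum <- 0
  for (i in seq_len(m)) {
    new_cluster <- k == 0L || (mz[i] - cent) / cent * 1e6 > tol_ppm
    if (new_cluster) {
      k <- k + 1L
      csum <- 0; wsum <- 0
    }
    cluster[i] <- k
    w <- if (weighted) intensity[i] else 1
    csum <- csum + w * mz[i]
    wsum <- wsum + w
    cent <- if (wsum > 0) csum / wsum else mz[i]
  }
  cluster
}

cluster_centroids <- function(members, mz, intensity, weighted) {
  vapply(members, function(idx) {
    if (weighted && sum(intensity[idx]) > 0) {
      sum(mz[idx] * intensity[idx]) / sum(intensity[idx])
    } else {
      mean(mz[idx])
    }
  }, numeric(1))
}

cluster_sample_sums <- function(members, intensity, sample_idx, n_samples) {
  out <- matrix(0, n_samples, length(members))
  for (k in seq_along(members)) {
    idx <- members[[k]]
    s <- rowsum(intensity[idx], sample_idx[idx])
    out[as.integer(rownames(s)), k] <- s[, 1L]
  }
  out
}
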