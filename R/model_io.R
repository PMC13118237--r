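#' Save an age-curve model to disk
#'
#' Scalars, selection and z-normalization parameters, the Z-bar curve and
#' spline settings go to JSON; the reference fingerprint matrix goes to a
#' companion CSV (`<path>.refmat.csv`, features in rows, grid ages in
#' columns, first column the feature m/z).
#'
#' @param model An `age_curve_model`.
#' @param path JSON output path.
#' @return Invisibly, `path`.
#' @export
save_age_model <- function(model, path) {
  stopifnot(inherits(model, "age_curve_model"))
  refmat_path <- paste0(path, ".refmat.csv")
  obj <- list(
    sex = model$sex,
    age_grid = model$age_grid,
    params = model$params[c("feature_index", "feature_mz", "mean", "sd")],
    zbar_curve = unname(model$zbar_curve),
    zbar_points = model$zbar_points,
    spline = model$spline,
    provenance = model$provenance,
    refmat_file = basename(refmat_path)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  ref <- data.frame(feature_mz = model$params$feature_mz,
                    model$reference_matrix, check.names = FALSE)
  names(ref) <- c("feature_mz", as.character(model$age_grid))
  data.table::fwrite(ref, refmat_path)
  invisible(path)
}

#' Load an age-curve model saved by [save_age_model()]
#'
#' @param path JSON path; the companion `*.refmat.csv` must sit beside it.
#' @return An `age_curve_model`.
#' @export
load_age_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  refmat_path <- file.path(dirname(path), obj$refmat_file)
  ref <- data.table::fread(refmat_path, data.table = FALSE)
  reference_matrix <- as.matrix(ref[, -1L, drop = FALSE])
  params <- structure(
    list(feature_index = as.integer(obj$params$feature_index),
         feature_mz = as.numeric(obj$params$feature_mz),
         mean = as.numeric(obj$params$mean),
         sd = as.numeric(obj$params$sd)),
    class = "zscore_params")
  age_grid <- as.integer(obj$age_grid)
  dimnames(reference_matrix) <- list(format_feature_mz(params$feature_mz),
                                     age_grid)
  structure(
    list(sex = obj$sex, age_grid = age_grid, params = params,
         reference_matrix = reference_matrix,
         zbar_curve = stats::setNames(as.numeric(obj$zbar_curve), age_grid),
         zbar_points = as.data.frame(obj$zbar_points),
         spline = obj$spline,
         provenance = obj$provenance),
    class = "age_curve_model"
  )
}
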