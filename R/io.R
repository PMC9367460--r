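#' Write and read volumes as NIfTI
#'
#' Volumes are stored as NIfTI files with the array transposed to the
#' conventional (x, y, z) fastest-first disk order, spacing in the pixdim
#' fields and the voxel-centred origin in the qform offset; on read they
#' are transposed back to the package's internal (z, y, x) axis order.
#' Masks round-trip bit-exactly (written as 0/1 integers); doses round-trip
#' to within single-precision-safe tolerance (written as float64, so in
#' practice exactly).
#'
#' @param obj A [dose_grid()] or [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly. `read_volume` returns a
#'   [dose_grid()] (default) or [binary_mask()] (`as = "mask"`).
#' @export
write_volume <- function(obj, path) {
  if (inherits(obj, "binary_mask")) {
    arr <- array(as.integer(obj$values), dim = obj$geometry$shape)
    kind <- "mask"
  } else if (inherits(obj, "dose_grid")) {
    arr <- obj$values
    kind <- obj$dose_kind
  } else stop("'obj' must be a dose_grid or binary_mask")
  g <- obj$geometry
  disk <- aperm(arr, c(3, 2, 1))              # (z,y,x) -> (x,y,z)
  img <- RNifti::asNifti(disk)
  RNifti::pixdim(img) <- rev(g$spacing)
  xf <- diag(c(rev(g$spacing), 1))
  xf[1:3, 4] <- rev(g$origin)
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param as `"dose"` (default), `"mask"`, or `"auto"` (mask iff all values
#'   are 0/1).
#' @param dose_kind Dose kind to stamp on a dose read, `"physical"` or
#'   `"BED"`.
#' @export
read_volume <- function(path, as = c("dose", "mask", "auto"),
                        dose_kind = "physical") {
  as <- match.arg(as)
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  disk <- as.array(img)
  if (length(dim(disk)) != 3L)
    stop("expected a 3D volume, got ", length(dim(disk)), "D")
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("volume is missing valid 'spacing' (pixdim) metadata")
  xf <- RNifti::xform(img)
  origin_disk <- xf[1:3, 4]
  arr <- aperm(disk, c(3, 2, 1))              # (x,y,z) -> (z,y,x)
  g <- grid_geometry(dim(arr), rev(pd[1:3]), rev(origin_disk))
  is_binary <- all(arr %in% c(0, 1))
  if (as == "mask" || (as == "auto" && is_binary)) {
    if (!is_binary) stop("volume is not binary; cannot read as mask")
    binary_mask(g, arr != 0)
  } else {
    dose_grid(g, arr, dose_kind = dose_kind)
  }
}

#' Read a per-patient clinical feature table
#'
#' Comma-separated, UTF-8, `.` decimal, header row required. Mandatory
#' columns are the clinical covariates (`smoking_status`, `copd`, `mevs`,
#' `ajcc_stage`); unknown columns are preserved as pass-through. Rows with
#' non-numeric entries in numeric columns are excluded, with the exclusions
#' reported in the `excluded_rows` attribute rather than aborting the run.
#'
#' @param path CSV file path.
#' @param required Mandatory column names.
#' @return Data frame of typed records, with attribute `excluded_rows`
#'   (integer row numbers dropped for malformed numeric values).
#' @export
read_patient_table <- function(path,
                               required = c("smoking_status", "copd", "mevs",
                                            "ajcc_stage")) {
  if (!file.exists(path)) stop("no such table file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  numeric_cols <- intersect(c("smoking_status", "copd", "mevs",
                              risk_feature_names(), plan_metric_names()),
                            names(tab))
  numeric_cols <- setdiff(numeric_cols, "ajcc_stage")
  bad_rows <- integer(0)
  for (col in numeric_cols) {
    if (is.numeric(tab[[col]])) next
    parsed <- suppressWarnings(as.numeric(tab[[col]]))
    bad_rows <- union(bad_rows, which(is.na(parsed) & !is.na(tab[[col]])))
    tab[[col]] <- parsed
  }
  if (length(bad_rows) > 0) {
    message("excluding ", length(bad_rows),
            " row(s) with non-numeric values in numeric columns: ",
            paste(sort(bad_rows), collapse = ", "))
    tab <- tab[-bad_rows, , drop = FALSE]
  }
  attr(tab, "excluded_rows") <- sort(bad_rows)
  tab
}

#' Run configuration
#'
#' Bundles the analysis thresholds, fractionation defaults, constraint set
#' and master seed, and round-trips losslessly through JSON.
#'
#' @param prob_threshold APT probability threshold (default 0.08).
#' @param dmean_threshold Pmap mean BED threshold in Gy (default 30.3).
#' @param min_relative_reduction Low-dose-cohort success rule (default 0.20).
#' @param prescription_dose,n_fractions Fractionation defaults.
#' @param alpha_beta_normal,alpha_beta_tumour BED alpha/beta ratios in Gy.
#' @param constraints A [constraint_set()].
#' @param seed Master seed (mandatory; no wall-clock seeding).
#' @return An object of class `run_config`.
#' @export
run_config <- function(prob_threshold = 0.08, dmean_threshold = 30.3,
                       min_relative_reduction = 0.20,
                       prescription_dose = 66, n_fractions = 33,
                       alpha_beta_normal = 3, alpha_beta_tumour = 10,
                       constraints = constraint_set(), seed = 1) {
  stopifnot(prob_threshold > 0, dmean_threshold > 0,
            min_relative_reduction > 0, inherits(constraints, "constraint_set"))
  if (is.null(seed) || !is.finite(seed)) stop("a numeric master seed is required")
  structure(list(prob_threshold = prob_threshold,
                 dmean_threshold = dmean_threshold,
                 min_relative_reduction = min_relative_reduction,
                 prescription_dose = prescription_dose,
                 n_fractions = n_fractions,
                 alpha_beta_normal = alpha_beta_normal,
                 alpha_beta_tumour = alpha_beta_tumour,
                 constraints = constraints, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$constraints <- list(constraints = config$constraints$constraints,
                        ptv95_floor = config$constraints$ptv95_floor,
                        ptv95_drop_tolerance =
                          config$constraints$ptv95_drop_tolerance)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cs <- constraint_set(
    constraints = as.data.frame(j$constraints$constraints),
    ptv95_floor = j$constraints$ptv95_floor,
    ptv95_drop_tolerance = j$constraints$ptv95_drop_tolerance)
  run_config(prob_threshold = j$prob_threshold,
             dmean_threshold = j$dmean_threshold,
             min_relative_reduction = j$min_relative_reduction,
             prescription_dose = j$prescription_dose,
             n_fractions = j$n_fractions,
             alpha_beta_normal = j$alpha_beta_normal,
             alpha_beta_tumour = j$alpha_beta_tumour,
             constraints = cs, seed = j$seed)
}
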