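#' Spatial transform between phantom and patient space
#'
#' A transform mapping phantom world coordinates (mm) to patient world
#' coordinates. Three kinds are supported:
#' \describe{
#'   \item{identity}{No motion; lattices may still differ.}
#'   \item{affine}{A 4x4 homogeneous matrix acting on world coordinates in
#'     (z, y, x) order, matching the package's array axis convention.}
#'   \item{displacement_field}{A per-voxel displacement (mm) defined on the
#'     \emph{target} (patient) lattice as a 4D array `(nz, ny, nx, 3)`; for
#'     each patient voxel it gives the offset from the patient world
#'     coordinate to the corresponding phantom world coordinate, i.e. the
#'     registration exported in reverse, which is the form resampling needs.}
#' }
#'
#' @param kind One of `"identity"`, `"affine"`, `"displacement_field"`.
#' @param parameters For `affine`, an invertible 4x4 matrix; for
#'   `displacement_field`, a 4D numeric array; ignored for `identity`.
#' @return An object of class `spatial_transform`.
#' @export
spatial_transform <- function(kind = c("identity", "affine",
                                       "displacement_field"),
                              parameters = NULL) {
  kind <- match.arg(kind)
  if (kind == "affine") {
    if (!is.matrix(parameters) || !identical(dim(parameters), c(4L, 4L)))
      stop("affine transform requires a 4x4 matrix")
    det_a <- det(parameters)
    if (!is.finite(det_a) || abs(det_a) < 1e-12)
      stop("singular affine matrix: not invertible")
  } else if (kind == "displacement_field") {
    if (!is.array(parameters) || length(dim(parameters)) != 4L ||
        dim(parameters)[4] != 3L)
      stop("displacement field must be a 4D array (nz, ny, nx, 3)")
  }
  structure(list(kind = kind, parameters = parameters),
            class = "spatial_transform")
}

#' Translation transform helper
#' @param shift_mm Numeric triple (z, y, x) translation in mm, phantom to
#'   patient.
#' @return An affine [spatial_transform()].
#' @export
translation_transform <- function(shift_mm) {
  stopifnot(length(shift_mm) == 3L)
  m <- diag(4)
  m[1:3, 4] <- as.numeric(shift_mm)
  spatial_transform("affine", m)
}

#' Invert an affine transform
#' @param t An identity or affine [spatial_transform()].
#' @return The inverse [spatial_transform()].
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "spatial_transform"))
  if (t$kind == "identity") return(t)
  if (t$kind != "affine")
    stop("only identity and affine transforms can be inverted analytically")
  spatial_transform("affine", solve(t$parameters))
}

# Voxel-centre world coordinates for every lattice voxel; N x 3 (z, y, x) mm.
lattice_world_coords <- function(geometry) {
  idx <- as.matrix(expand.grid(z = seq_len(geometry$shape[1]),
                               y = seq_len(geometry$shape[2]),
                               x = seq_len(geometry$shape[3])))
  sweep(sweep(idx - 1, 2, geometry$spacing, `*`), 2, geometry$origin, `+`)
}

#' Transfer a phantom-defined mask into a patient lattice
#'
#' Resamples a binary mask (typically the Pmap sub-region defined on the
#' reference thoracic phantom) onto a patient lattice by inverse-lookup
#' nearest-neighbour sampling: each patient voxel centre is mapped back to
#' phantom space through the inverse of `t` and takes the value of the
#' nearest phantom voxel. No partial-volume thresholding is applied, so
#' labels stay binary.
#'
#' @param pmap_phantom A [binary_mask()] on the phantom lattice.
#' @param t A [spatial_transform()] mapping phantom world to patient world.
#' @param target A [grid_geometry()] describing the patient lattice.
#' @return A [binary_mask()] on `target`; empty with a warning when the
#'   region maps entirely outside the patient grid.
#' @export
map_pmap_to_patient <- function(pmap_phantom, t, target) {
  stopifnot(inherits(pmap_phantom, "binary_mask"),
            inherits(t, "spatial_transform"),
            inherits(target, "grid_geometry"))
  w_target <- lattice_world_coords(target)
  w_source <- switch(t$kind,
    identity = w_target,
    affine = {
      inv <- solve(t$parameters)
      h <- cbind(w_target, 1) %*% t(inv)
      h[, 1:3, drop = FALSE]
    },
    displacement_field = {
      dfield <- t$parameters
      if (!identical(as.integer(dim(dfield)[1:3]), target$shape))
        stop("displacement field lattice does not match the target geometry")
      w_target + matrix(dfield, ncol = 3L)
    })
  g <- pmap_phantom$geometry
  idx <- round(sweep(sweep(w_source, 2, g$origin, `-`), 2, g$spacing, `/`)) + 1
  valid <- idx[, 1] >= 1 & idx[, 1] <= g$shape[1] &
           idx[, 2] >= 1 & idx[, 2] <= g$shape[2] &
           idx[, 3] >= 1 & idx[, 3] <= g$shape[3]
  vals <- logical(nrow(idx))
  if (any(valid))
    vals[valid] <- pmap_phantom$values[idx[valid, , drop = FALSE]]
  out <- binary_mask(target, array(vals, dim = target$shape))
  if (mask_voxel_count(out) == 0L && mask_voxel_count(pmap_phantom) > 0L)
    warning("mapped region falls entirely outside the target grid")
  out
}

#' Registration quality as a Dice coefficient
#'
#' Dice overlap between the phantom's hybrid VOI (lungs union heart) and the
#' patient's hybrid VOI warped into phantom space — the registration QA
#' number reported per patient and as a cohort mean.
#'
#' @param phantom_voi,mapped_patient_voi [binary_mask()] objects on one
#'   lattice.
#' @return Dice coefficient in `[0, 1]`.
#' @export
registration_qa <- function(phantom_voi, mapped_patient_voi) {
  dice(phantom_voi, mapped_patient_voi)
}
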