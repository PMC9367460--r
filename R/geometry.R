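#' Voxel lattice geometry
#'
#' Describes the regular 3D voxel lattice every dose grid and structure mask
#' in a plan lives on. Array axis order is fixed as (z, y, x); world
#' coordinates are voxel-centred, in millimetres, with `origin` the world
#' coordinate of the centre of voxel index (1, 1, 1).
#'
#' @param shape Integer triple `(nz, ny, nx)`, all entries >= 1.
#' @param spacing Numeric triple of voxel spacings in mm, all > 0.
#' @param origin Numeric triple, world mm coordinate of the first voxel
#'   centre. Default `c(0, 0, 0)`.
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(c(64, 64, 64), spacing = c(4, 4, 4))
#' voxel_volume_mm3(g)
#' @export
grid_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite values (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d x %d (z,y,x), spacing %s mm, origin %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Voxel volume of a lattice
#'
#' @param geometry A [grid_geometry()].
#' @return Volume of one voxel in mm^3.
#' @export
voxel_volume_mm3 <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  prod(geometry$spacing)
}

geometry_equal <- function(a, b, tol = 1e-6) {
  if (!identical(a$shape, b$shape)) return("shape")
  if (any(abs(a$spacing - b$spacing) > tol)) return("spacing")
  if (any(abs(a$origin - b$origin) > tol)) return("origin")
  NULL
}

#' Dose grid on a voxel lattice
#'
#' @param geometry A [grid_geometry()].
#' @param values 3D numeric array of dose in Gy, dimensions equal to
#'   `geometry$shape`; all values finite and >= 0.
#' @param dose_kind `"physical"` or `"BED"` (biologically effective dose).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(geometry, values, dose_kind = c("physical", "BED")) {
  stopifnot(inherits(geometry, "grid_geometry"))
  dose_kind <- match.arg(dose_kind)
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), geometry$shape))
    stop(sprintf("dose array dims (%s) do not match geometry shape (%s)",
                 paste(dim(values), collapse = ","),
                 paste(geometry$shape, collapse = ",")))
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and >= 0")
  storage.mode(values) <- "double"
  structure(list(geometry = geometry, values = values, dose_kind = dose_kind),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s dose, range [%.3g, %.3g] Gy on ", x$dose_kind,
              min(x$values), max(x$values)))
  print(x$geometry)
  invisible(x)
}

#' Binary structure mask on a voxel lattice
#'
#' @param geometry A [grid_geometry()].
#' @param values 3D logical (or 0/1) array, dimensions equal to
#'   `geometry$shape`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(geometry, values) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), geometry$shape))
    stop(sprintf("mask array dims (%s) do not match geometry shape (%s)",
                 paste(dim(values), collapse = ","),
                 paste(geometry$shape, collapse = ",")))
  if (is.numeric(values)) {
    if (any(!values %in% c(0, 1))) stop("numeric mask values must be 0/1")
    values <- array(values != 0, dim = dim(values))
  }
  if (!is.logical(values)) stop("mask values must be logical or 0/1")
  if (any(is.na(values))) stop("mask values must not be NA")
  structure(list(geometry = geometry, values = values), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d voxels (%.3f cc) on ", mask_voxel_count(x),
              mask_volume_cc(x)))
  print(x$geometry)
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask A [binary_mask()].
#' @return Integer count of TRUE voxels.
#' @export
mask_voxel_count <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values)
}

#' Mask volume in cubic centimetres
#'
#' Voxel count times voxel volume, converted mm^3 to cc.
#'
#' @param mask A [binary_mask()].
#' @return Volume in cc.
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  mask_voxel_count(mask) * voxel_volume_mm3(mask$geometry) / 1000
}

#' Union of two masks
#'
#' Voxelwise logical OR of two masks sharing one lattice, e.g. building the
#' hybrid lungs-plus-heart registration VOI or the combined-lungs structure.
#'
#' @param a,b [binary_mask()] objects on the same lattice.
#' @return A [binary_mask()].
#' @export
union_masks <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  bad <- geometry_equal(a$geometry, b$geometry)
  if (!is.null(bad))
    stop(sprintf(
      "mask geometries differ in '%s': (%s | %s | %s) vs (%s | %s | %s)", bad,
      paste(a$geometry$shape, collapse = ","),
      paste(a$geometry$spacing, collapse = ","),
      paste(a$geometry$origin, collapse = ","),
      paste(b$geometry$shape, collapse = ","),
      paste(b$geometry$spacing, collapse = ","),
      paste(b$geometry$origin, collapse = ",")))
  binary_mask(a$geometry, a$values | b$values)
}

#' Intersection of two masks
#' @inheritParams union_masks
#' @return A [binary_mask()].
#' @export
intersect_masks <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  bad <- geometry_equal(a$geometry, b$geometry)
  if (!is.null(bad)) stop(sprintf("mask geometries differ in '%s'", bad))
  binary_mask(a$geometry, a$values & b$values)
}

#' Check that objects share one voxel lattice
#'
#' All pipeline stages require dose and structures on a single shared
#' lattice; this validates that assumption up front. Geometries must agree
#' within 1e-6 mm on spacing and origin and exactly on shape.
#'
#' @param objects List of [dose_grid()] / [binary_mask()] objects (at least
#'   one).
#' @param tol Spacing/origin tolerance in mm.
#' @return Invisibly `TRUE`; errors with a report naming the first differing
#'   geometry field otherwise.
#' @export
validate_same_lattice <- function(objects, tol = 1e-6) {
  if (!is.list(objects) || length(objects) < 1L)
    stop("'objects' must be a non-empty list")
  geoms <- lapply(objects, function(o) {
    if (!inherits(o, c("dose_grid", "binary_mask")))
      stop("objects must be dose_grid or binary_mask")
    o$geometry
  })
  ref <- geoms[[1]]
  for (i in seq_along(geoms)[-1]) {
    bad <- geometry_equal(ref, geoms[[i]], tol)
    if (!is.null(bad))
      stop(sprintf("lattice mismatch: object %d differs from object 1 in '%s'",
                   i, bad))
  }
  invisible(TRUE)
}

#' Structure set for one patient
#'
#' Named binary masks on one shared lattice. The canonical structures are
#' `PTV`, `LungH` (homolateral lung), `LungC` (contralateral lung), `Heart`,
#' `SpinalCord`, `Pmap` and optionally `2Lungs`; when `2Lungs` is absent it
#' is derived as `LungH` union `LungC`.
#'
#' @param masks Named list of [binary_mask()] objects.
#' @param geometry Optional [grid_geometry()]; defaults to the first mask's.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, geometry = NULL) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("'masks' must be a named list of binary_mask objects")
  if (is.null(geometry)) geometry <- masks[[1]]$geometry
  validate_same_lattice(masks)
  bad <- geometry_equal(geometry, masks[[1]]$geometry)
  if (!is.null(bad)) stop(sprintf("masks do not match geometry in '%s'", bad))
  required <- c("PTV", "LungH", "LungC", "Heart", "SpinalCord", "Pmap")
  missing <- setdiff(required, names(masks))
  if (length(missing) > 0)
    stop("missing required structures: ", paste(missing, collapse = ", "))
  if (mask_voxel_count(masks$PTV) == 0L) stop("PTV mask must be non-empty")
  if (!"2Lungs" %in% names(masks))
    masks[["2Lungs"]] <- union_masks(masks$LungH, masks$LungC)
  structure(list(geometry = geometry, masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  counts <- vapply(x$masks, mask_voxel_count, integer(1))
  cat("<structure_set> ", paste(sprintf("%s:%d", names(counts), counts),
                                collapse = " "), "\n")
  print(x$geometry)
  invisible(x)
}
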