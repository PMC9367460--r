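#' Dice overlap coefficient of two masks
#'
#' `2|A & B| / (|A| + |B|)`. When both masks are empty the coefficient is
#' undefined; by convention 0 is returned with a warning so downstream ROC
#' analysis stays computable.
#'
#' @param a,b [binary_mask()] objects on the same lattice.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  bad <- geometry_equal(a$geometry, b$geometry)
  if (!is.null(bad)) stop(sprintf("mask geometries differ in '%s'", bad))
  na <- sum(a$values)
  nb <- sum(b$values)
  if (na + nb == 0L) {
    warning("both masks empty: Dice undefined, returning 0 by convention")
    return(0)
  }
  2 * sum(a$values & b$values) / (na + nb)
}

#' Conformity index (IC)
#'
#' Ratio of the prescription isodose volume (PIV; volume of the whole grid
#' receiving at least the prescription dose, inclusive threshold) to the PTV
#' volume. The PIV is evaluated over the full grid, not restricted to a body
#' contour.
#'
#' @param d A physical [dose_grid()].
#' @param ptv Non-empty PTV [binary_mask()] on the same lattice.
#' @param fx A [fractionation()].
#' @return IC, dimensionless (>= 0; 0 when nothing reaches prescription).
#' @export
conformity_index <- function(d, ptv, fx) {
  stopifnot(inherits(d, "dose_grid"), inherits(ptv, "binary_mask"),
            inherits(fx, "fractionation"))
  if (d$dose_kind != "physical")
    stop("conformity index is evaluated on physical dose")
  validate_same_lattice(list(d, ptv))
  n_ptv <- mask_voxel_count(ptv)
  if (n_ptv == 0L) stop("empty structure: PTV mask is empty")
  piv <- sum(d$values >= fx$prescription_dose)
  piv / n_ptv
}

#' Heterogeneity index (HIV)
#'
#' `D95% / D5%` within the PTV, both from the cumulative DVH with linear
#' interpolation. Always in (0, 1] because the cumulative DVH is monotone.
#'
#' @param d A [dose_grid()].
#' @param ptv Non-empty PTV [binary_mask()].
#' @param bin_width DVH bin width in Gy.
#' @return HIV in (0, 1].
#' @export
heterogeneity_index <- function(d, ptv, bin_width = 0.1) {
  curve <- cumulative_dvh(d, ptv, bin_width = bin_width)
  d95 <- d_at_volume(curve, 95)
  d5 <- d_at_volume(curve, 5)
  if (d5 <= 0)
    stop("heterogeneity index undefined: D5% is zero")
  d95 / d5
}
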