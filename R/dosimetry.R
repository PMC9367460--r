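#' Fractionation scheme
#'
#' Total prescription dose and number of fractions for a plan. Dose per
#' fraction must fall in (0, 20] Gy.
#'
#' @param prescription_dose Total prescription dose in Gy (> 0).
#' @param n_fractions Positive integer number of fractions.
#' @return An object of class `fractionation`.
#' @examples
#' fractionation(66, 33)   # 2 Gy / fraction
#' @export
fractionation <- function(prescription_dose, n_fractions) {
  prescription_dose <- as.numeric(prescription_dose)
  n_fractions <- as.integer(n_fractions)
  if (!is.finite(prescription_dose) || prescription_dose <= 0)
    stop("'prescription_dose' must be > 0 Gy")
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("'n_fractions' must be a positive integer")
  d <- prescription_dose / n_fractions
  if (d > 20)
    stop(sprintf("dose per fraction %.2f Gy exceeds 20 Gy", d))
  structure(list(prescription_dose = prescription_dose,
                 n_fractions = n_fractions),
            class = "fractionation")
}

#' Convert a physical dose grid to biologically effective dose
#'
#' Standard linear-quadratic BED with the voxel's per-fraction dose taken as
#' the voxel dose divided by the fraction number:
#' `BED(v) = D(v) * (1 + (D(v)/n) / (alpha/beta))`.
#' The field convention is alpha/beta = 3 Gy for normal (non-tumour) tissue
#' and 10 Gy for tumour volumes.
#'
#' @param d A physical [dose_grid()].
#' @param fx A [fractionation()] providing the fraction number.
#' @param alpha_beta Alpha/beta ratio in Gy (> 0).
#' @return A [dose_grid()] with `dose_kind = "BED"`.
#' @examples
#' g <- grid_geometry(c(2, 2, 2), c(1, 1, 1))
#' d <- dose_grid(g, array(60, c(2, 2, 2)))
#' to_bed(d, fractionation(60, 30), alpha_beta = 10)$values[1]  # 72 Gy
#' @export
to_bed <- function(d, fx, alpha_beta) {
  stopifnot(inherits(d, "dose_grid"), inherits(fx, "fractionation"))
  if (d$dose_kind != "physical")
    stop("'d' must be a physical dose grid, not already BED")
  if (!is.numeric(alpha_beta) || !is.finite(alpha_beta) || alpha_beta <= 0)
    stop("'alpha_beta' must be > 0 Gy")
  per_fraction <- d$values / fx$n_fractions
  bed <- d$values * (1 + per_fraction / alpha_beta)
  dose_grid(d$geometry, bed, dose_kind = "BED")
}

in_mask_doses <- function(d, voi) {
  stopifnot(inherits(d, "dose_grid"), inherits(voi, "binary_mask"))
  validate_same_lattice(list(d, voi))
  if (mask_voxel_count(voi) == 0L)
    stop("empty structure: cannot compute dose metrics on an empty VOI")
  d$values[voi$values]
}

#' Cumulative dose-volume histogram
#'
#' Fraction of VOI voxels receiving at least each dose edge (inclusive).
#' Edges run from 0 past the in-mask maximum in steps of `bin_width`.
#'
#' @param d A [dose_grid()].
#' @param voi A non-empty [binary_mask()] on the same lattice.
#' @param bin_width Histogram bin width in Gy (default 0.1).
#' @return An object of class `dvh_curve`: list with `dose_edges` (Gy) and
#'   `cum_volume_fraction` in `[0, 1]`, non-increasing, starting at 1.
#' @export
cumulative_dvh <- function(d, voi, bin_width = 0.1) {
  if (!is.numeric(bin_width) || bin_width <= 0) stop("'bin_width' must be > 0")
  doses <- in_mask_doses(d, voi)
  n <- length(doses)
  edges <- seq(0, max(doses) + bin_width, by = bin_width)
  sorted <- sort(doses)
  # fraction with dose >= edge, inclusive: count via binary search on sorted
  below <- findInterval(edges - 1e-12, sorted)   # strictly < edge
  frac <- (n - below) / n
  structure(list(dose_edges = edges, cum_volume_fraction = frac),
            class = "dvh_curve")
}

#' Volume receiving at least a dose level (Vx)
#'
#' Percentage of the VOI receiving at least `x` Gy, computed by an exact
#' inclusive voxel count (ties at the threshold count as covered), not from
#' a binned curve.
#'
#' @inheritParams cumulative_dvh
#' @param x Dose threshold in Gy.
#' @return Percentage in `[0, 100]`.
#' @export
v_at_dose <- function(d, voi, x) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  doses <- in_mask_doses(d, voi)
  100 * sum(doses >= x) / length(doses)
}

#' Dose received by at least q% of the volume (Dq%)
#'
#' The largest DVH dose edge at which the cumulative volume fraction is
#' still at least `q/100` — i.e. the dose covering q% of the VOI, resolved
#' at the histogram's bin width. Within one bin width of the exact order
#' statistic (the lower edge of the bin the quantile falls in), which keeps
#' identities such as D95 = D5 on a uniformly irradiated VOI exact;
#' decrease `bin_width` in [cumulative_dvh()] when finer resolution is
#' needed. Non-increasing in `q`, so D95 <= D5 always.
#'
#' @param curve A `dvh_curve` from [cumulative_dvh()].
#' @param q Volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
d_at_volume <- function(curve, q) {
  if (!inherits(curve, "dvh_curve")) stop("'curve' must be a dvh_curve")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 100)
    stop("'q' must be in (0, 100]")
  edges <- curve$dose_edges
  frac <- curve$cum_volume_fraction
  if (length(edges) != length(frac) || is.unsorted(edges, strictly = TRUE) ||
      any(diff(frac) > 1e-12))
    stop("malformed DVH curve")
  covered <- which(frac >= q / 100 - 1e-12)
  if (length(covered) == 0L) return(edges[1])
  edges[max(covered)]
}

#' Mean and maximum dose in a VOI
#'
#' @inheritParams cumulative_dvh
#' @return Named numeric vector `c(dmean, dmax)` in Gy.
#' @export
dose_stats <- function(d, voi) {
  doses <- in_mask_doses(d, voi)
  c(dmean = mean(doses), dmax = max(doses))
}

#' PTV coverage by the 95% isodose (PTV95)
#'
#' Percentage of the PTV receiving at least 95% of the prescription dose.
#'
#' @param d A physical [dose_grid()].
#' @param ptv Non-empty PTV [binary_mask()].
#' @param fx A [fractionation()].
#' @return PTV95 as a percentage.
#' @export
ptv_coverage <- function(d, ptv, fx) {
  stopifnot(inherits(fx, "fractionation"))
  if (d$dose_kind != "physical")
    stop("PTV coverage is evaluated on physical dose")
  v_at_dose(d, ptv, 0.95 * fx$prescription_dose)
}

# Table-layout of the metric panel: which Vx/Dmean/Dmax per structure.
panel_spec <- list(
  LungH      = list(v = c(5, 10, 13, 20, 30), dmean = TRUE,  dmax = TRUE),
  LungC      = list(v = c(5, 10, 13, 20, 30), dmean = TRUE,  dmax = TRUE),
  `2Lungs`   = list(v = c(13, 20, 30),        dmean = TRUE,  dmax = FALSE),
  Heart      = list(v = c(30, 40),            dmean = TRUE,  dmax = FALSE),
  SpinalCord = list(v = numeric(0),           dmean = FALSE, dmax = TRUE)
)

metric_key <- function(structure, what) {
  s <- tolower(gsub("^2", "two_", structure))
  paste0(s, "_", what)
}

#' Names of the plan-metric panel fields
#' @return Character vector of metric field names in panel order.
#' @export
plan_metric_names <- function() {
  out <- "ptv95"
  for (s in names(panel_spec)) {
    p <- panel_spec[[s]]
    for (x in p$v) out <- c(out, metric_key(s, paste0("v", x)))
    if (p$dmean) out <- c(out, metric_key(s, "dmean"))
    if (p$dmax) out <- c(out, metric_key(s, "dmax"))
  }
  c(out, "pmap_dmean_bed", "ic", "hiv")
}

#' Full DVH/index metric panel for one plan
#'
#' Computes the standard panel for a thoracic plan: PTV95; V5/V10/V13/V20/V30,
#' Dmean and Dmax for each lung; V13/V20/V30 and Dmean for both lungs
#' combined; V30/V40 and Dmean for the heart; spinal-cord Dmax; the mean
#' Pmap dose; and the conformity (IC) and heterogeneity (HIV) indices.
#'
#' The Pmap mean dose is computed on the BED grid with alpha/beta = 3 Gy —
#' the scale on which the 30.3 Gy risk threshold is defined — while all other
#' organ-at-risk metrics are physical dose by default; set `bed_all = TRUE`
#' to convert every metric to BED (alpha/beta 3 for OARs, 10 for the PTV).
#'
#' @param d A physical [dose_grid()].
#' @param ss A [structure_set()] with all required structures.
#' @param fx A [fractionation()].
#' @param bed_all Compute the whole panel on BED grids instead of physical
#'   dose. Default `FALSE`.
#' @param alpha_beta_normal,alpha_beta_tumour Alpha/beta ratios (Gy) used for
#'   BED conversion of normal tissue and tumour metrics.
#' @return An object of class `plan_metrics`: named numeric vector over
#'   [plan_metric_names()].
#' @export
compute_plan_metrics <- function(d, ss, fx, bed_all = FALSE,
                                 alpha_beta_normal = 3,
                                 alpha_beta_tumour = 10) {
  stopifnot(inherits(d, "dose_grid"), inherits(ss, "structure_set"),
            inherits(fx, "fractionation"))
  validate_same_lattice(c(list(d), ss$masks))
  bed_normal <- to_bed(d, fx, alpha_beta_normal)
  d_oar <- if (bed_all) bed_normal else d
  d_ptv <- if (bed_all) to_bed(d, fx, alpha_beta_tumour) else d

  out <- c(ptv95 = ptv_coverage(d, ss$masks$PTV, fx))
  for (s in names(panel_spec)) {
    if (!s %in% names(ss$masks)) stop("missing structure: ", s)
    p <- panel_spec[[s]]
    m <- ss$masks[[s]]
    for (x in p$v) out[metric_key(s, paste0("v", x))] <- v_at_dose(d_oar, m, x)
    if (p$dmean || p$dmax) {
      st <- dose_stats(d_oar, m)
      if (p$dmean) out[metric_key(s, "dmean")] <- st[["dmean"]]
      if (p$dmax) out[metric_key(s, "dmax")] <- st[["dmax"]]
    }
  }
  out["pmap_dmean_bed"] <- dose_stats(bed_normal, ss$masks$Pmap)[["dmean"]]
  out["ic"] <- conformity_index(d, ss$masks$PTV, fx)
  out["hiv"] <- tryCatch(heterogeneity_index(d_ptv, ss$masks$PTV),
                         error = function(e) {
                           warning("heterogeneity index undefined (D5% = 0); ",
                                   "reported as NA")
                           NA_real_
                         })
  structure(out[plan_metric_names()], class = "plan_metrics")
}

#' Build a plan_metrics object from named values
#'
#' For records whose DVH panel comes from an external planning system rather
#' than from dose grids (e.g. printed plan reports). Fields not supplied are
#' `NA`.
#'
#' @param ... Named metric values, names among [plan_metric_names()].
#' @return A `plan_metrics` object.
#' @export
plan_metrics_from_values <- function(...) {
  vals <- c(...)
  unknown <- setdiff(names(vals), plan_metric_names())
  if (length(unknown) > 0)
    stop("unknown metric fields: ", paste(unknown, collapse = ", "))
  out <- stats::setNames(rep(NA_real_, length(plan_metric_names())),
                         plan_metric_names())
  out[names(vals)] <- vals
  structure(out, class = "plan_metrics")
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat("<plan_metrics>\n")
  print(round(unclass(x), 3))
  invisible(x)
}
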