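# Shift a 3D array by k voxels along one axis, zero-filling the vacated
# slab. Used by the separable Gaussian blur.
shift_axis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  if (abs(k) >= n) return(out)
  src <- lapply(d, seq_len)
  dst <- src
  if (k >= 0) {
    src[[axis]] <- seq_len(n - k)
    dst[[axis]] <- seq_len(n - k) + k
  } else {
    src[[axis]] <- seq_len(n + k) - k
    dst[[axis]] <- seq_len(n + k)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable 3D Gaussian blur with zero padding; sigma in voxels per axis.
gauss_blur3 <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    offs <- -r:r
    w <- stats::dnorm(offs, sd = s)
    w <- w / sum(w)
    acc <- array(0, dim(a))
    for (j in seq_along(offs)) acc <- acc + w[j] * shift_axis(a, offs[j], axis)
    a <- acc
  }
  a
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic thoracic phantom specification
#'
#' Geometry and organ parameters for the synthetic phantom: two lung
#' ellipsoids, a heart ellipsoid carved out of the lungs, a spinal-cord
#' cylinder, a spherical PTV inside the homolateral (right) lung, and a
#' Pmap box in the posterior right lung. Centres/radii are in voxel units
#' (1-based indices, axis order z, y, x); +y is posterior and low x is the
#' patient's right. The default lattice is 64x64x64 at 4 mm isotropic.
#'
#' @param shape,spacing,origin Lattice parameters, see [grid_geometry()].
#' @param lungh_center,lungh_radii,lungc_center,lungc_radii Lung ellipsoids.
#' @param heart_center,heart_radii Heart ellipsoid.
#' @param cord_center_yx,cord_radius Spinal-cord cylinder (runs along z).
#' @param ptv_center,ptv_radius PTV sphere (must lie inside LungH).
#' @param pmap_box List of `z`, `y`, `x` index ranges (each `c(lo, hi)`)
#'   for the Pmap region; intersected with LungH.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(4, 4, 4),
                         origin = c(0, 0, 0),
                         lungh_center = c(32, 32, 20),
                         lungh_radii = c(24, 18, 11),
                         lungc_center = c(32, 32, 45),
                         lungc_radii = c(24, 18, 11),
                         heart_center = c(34, 36, 38),
                         heart_radii = c(10, 9, 9),
                         cord_center_yx = c(54, 32), cord_radius = 2,
                         ptv_center = c(32, 34, 20), ptv_radius = 6,
                         pmap_box = list(z = c(26, 38), y = c(41, 49),
                                         x = c(12, 24))) {
  if (ptv_radius <= 0) stop("'ptv_radius' must be > 0")
  if (cord_radius <= 0) stop("'cord_radius' must be > 0")
  structure(list(geometry = grid_geometry(shape, spacing, origin),
                 lungh_center = lungh_center, lungh_radii = lungh_radii,
                 lungc_center = lungc_center, lungc_radii = lungc_radii,
                 heart_center = heart_center, heart_radii = heart_radii,
                 cord_center_yx = cord_center_yx, cord_radius = cord_radius,
                 ptv_center = ptv_center, ptv_radius = ptv_radius,
                 pmap_box = pmap_box),
            class = "phantom_spec")
}

index_grids <- function(shape) {
  list(z = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), shape),
       y = array(rep(rep(seq_len(shape[2]), each = shape[1]),
                     times = shape[3]), shape),
       x = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape))
}

ellipsoid_mask <- function(g, idx, center, radii) {
  v <- ((idx$z - center[1]) / radii[1])^2 +
       ((idx$y - center[2]) / radii[2])^2 +
       ((idx$x - center[3]) / radii[3])^2 <= 1
  binary_mask(g, v)
}

#' Generate the synthetic thoracic phantom
#'
#' Builds the structure set from a [phantom_spec()] and validates the
#' anatomical invariants: the PTV sphere is contained in the homolateral
#' lung, the Pmap region is non-empty and lies in the posterior right
#' octant of the lungs, and the spinal cord is disjoint from both lungs.
#' The construction is deterministic (no randomness).
#'
#' @param spec A [phantom_spec()].
#' @return A [structure_set()] with PTV, LungH, LungC, Heart, SpinalCord,
#'   Pmap and 2Lungs.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  idx <- index_grids(g$shape)
  lungh <- ellipsoid_mask(g, idx, spec$lungh_center, spec$lungh_radii)
  lungc <- ellipsoid_mask(g, idx, spec$lungc_center, spec$lungc_radii)
  heart <- ellipsoid_mask(g, idx, spec$heart_center, spec$heart_radii)
  # lungs exclude the heart so the lung masks stay air-only
  lungh <- binary_mask(g, lungh$values & !heart$values)
  lungc <- binary_mask(g, lungc$values & !heart$values)
  cord <- binary_mask(g, (idx$y - spec$cord_center_yx[1])^2 +
                         (idx$x - spec$cord_center_yx[2])^2 <=
                         spec$cord_radius^2)
  ptv <- ellipsoid_mask(g, idx, spec$ptv_center, rep(spec$ptv_radius, 3))
  bx <- spec$pmap_box
  pmap_vals <- idx$z >= bx$z[1] & idx$z <= bx$z[2] &
               idx$y >= bx$y[1] & idx$y <= bx$y[2] &
               idx$x >= bx$x[1] & idx$x <= bx$x[2] & lungh$values
  pmap <- binary_mask(g, pmap_vals)

  if (mask_voxel_count(ptv) == 0L) stop("unplaceable PTV: empty mask")
  if (any(ptv$values & !lungh$values))
    stop("unplaceable PTV: not contained in the homolateral lung")
  if (mask_voxel_count(pmap) == 0L)
    stop("unplaceable Pmap: empty after intersecting with the lung")
  cen <- sapply(idx, function(a) mean(a[pmap$values]))
  if (cen[["y"]] <= g$shape[2] / 2)
    stop("Pmap centroid is not in the posterior half")
  if (cen[["x"]] >= g$shape[3] / 2)
    stop("Pmap centroid is not in the right half")
  if (any(cord$values & (lungh$values | lungc$values)))
    stop("spinal cord overlaps the lungs")

  structure_set(list(PTV = ptv, LungH = lungh, LungC = lungc, Heart = heart,
                     SpinalCord = cord, Pmap = pmap))
}

#' Plan-painter specification
#'
#' Parameters of the synthetic dose painter that emulates a paired
#' initial/optimized VMAT plan by direct dose sculpting. The initial plan
#' is the sum of three smooth fields plus voxel noise:
#' \itemize{
#'   \item a target field: prescription-level dose inside the PTV with an
#'     error-function penumbra profile in the distance from the (spherical)
#'     PTV surface, slightly hot inside (`hotspot_factor`) and rolling off
#'     so PTV-edge voxels sit near `edge_dose_fraction` of prescription —
#'     which sets realistic PTV95, conformity and heterogeneity values;
#'   \item a posterior dose bath: `posterior_spill * Rx` at the Pmap
#'     bounding box, decaying as a Gaussian in the distance from the box —
#'     the knob that drives the Pmap mean dose;
#'   \item a broad low-dose body bath centred on the PTV, standing in for
#'     the arc's entrance/exit dose over the lungs, heart and cord.
#' }
#' The optimized plan multiplies the initial dose by a smooth attenuation
#' field with the shape of the posterior bath, forced to 1 inside the PTV
#' (so the PTV dose distribution is untouched voxel-for-voxel) and scaled
#' to hit the requested relative reduction of the Pmap mean dose; when
#' PTV/Pmap overlap caps the attainable reduction below the target the
#' scale saturates and the pair is flagged not achievable.
#'
#' @param fx A [fractionation()] (default 66 Gy in 33 fractions).
#' @param penumbra_sigma Penumbra width in mm (default 5).
#' @param posterior_spill Dimensionless amplitude (>= 0) of the posterior
#'   dose bath over the Pmap region (default 0.30).
#' @param pmap_reduction_target Requested relative reduction of the Pmap
#'   mean physical dose, in `[0, 1)` (default 0.30).
#' @param noise_sd Additive Gaussian dose noise in Gy (default 0.5).
#' @param spill_sigma Decay length of the posterior bath in mm (default 15).
#' @param hotspot_factor Peak target dose as a fraction of prescription
#'   (default 1.025).
#' @param edge_dose_fraction Target dose at the PTV surface as a fraction
#'   of prescription (default 0.945).
#' @param body_bath_amp,body_bath_sigma Amplitude (fraction of Rx) and
#'   Gaussian width (mm) of the broad body bath (defaults 0.15 and 60).
#' @param seed RNG seed for the noise field.
#' @return An object of class `plan_painter_spec`.
#' @export
plan_painter_spec <- function(fx = fractionation(66, 33), penumbra_sigma = 5,
                              posterior_spill = 0.30,
                              pmap_reduction_target = 0.30, noise_sd = 0.5,
                              spill_sigma = 15, hotspot_factor = 1.025,
                              edge_dose_fraction = 0.945,
                              body_bath_amp = 0.15, body_bath_sigma = 60,
                              seed = 1) {
  stopifnot(inherits(fx, "fractionation"))
  if (posterior_spill < 0) stop("'posterior_spill' must be >= 0")
  if (pmap_reduction_target < 0 || pmap_reduction_target >= 1)
    stop("'pmap_reduction_target' must be in [0, 1)")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (edge_dose_fraction >= hotspot_factor)
    stop("'edge_dose_fraction' must be below 'hotspot_factor'")
  structure(list(fx = fx, penumbra_sigma = penumbra_sigma,
                 posterior_spill = posterior_spill,
                 pmap_reduction_target = pmap_reduction_target,
                 noise_sd = noise_sd, spill_sigma = spill_sigma,
                 hotspot_factor = hotspot_factor,
                 edge_dose_fraction = edge_dose_fraction,
                 body_bath_amp = body_bath_amp,
                 body_bath_sigma = body_bath_sigma, seed = seed),
            class = "plan_painter_spec")
}

# Per-voxel mm coordinates along each axis (relative to the lattice, origin
# ignored: the painter only needs in-grid distances).
mm_grids <- function(g) {
  idx <- index_grids(g$shape)
  list(z = (idx$z - 1) * g$spacing[1],
       y = (idx$y - 1) * g$spacing[2],
       x = (idx$x - 1) * g$spacing[3])
}

#' Paint a paired initial/optimized synthetic plan
#'
#' @param ss A [structure_set()] (e.g. from [generate_phantom()]).
#' @param spec A [plan_painter_spec()].
#' @return List with `initial` and `optimized` [dose_grid()]s (physical
#'   dose), the `achieved_reduction` of the Pmap mean physical dose, and
#'   `achievable` (`FALSE` when PTV/Pmap overlap caps the attainable
#'   reduction below the target).
#' @export
paint_plan_pair <- function(ss, spec = plan_painter_spec()) {
  stopifnot(inherits(ss, "structure_set"), inherits(spec, "plan_painter_spec"))
  g <- ss$geometry
  rx <- spec$fx$prescription_dose
  ptv <- ss$masks$PTV$values
  pmap <- ss$masks$Pmap$values
  mm <- mm_grids(g)

  # target field: erf penumbra profile in distance from the equivalent
  # PTV sphere surface (centroid + equivalent radius of the mask)
  cen <- c(mean(mm$z[ptv]), mean(mm$y[ptv]), mean(mm$x[ptv]))
  r_mm <- (3 * sum(ptv) * voxel_volume_mm3(g) / (4 * pi))^(1 / 3)
  d_cen <- sqrt((mm$z - cen[1])^2 + (mm$y - cen[2])^2 + (mm$x - cen[3])^2)
  d_surf <- d_cen - r_mm
  sig <- spec$penumbra_sigma
  d0 <- stats::qnorm(spec$edge_dose_fraction / spec$hotspot_factor) * sig
  base <- rx * spec$hotspot_factor * stats::pnorm((d0 - d_surf) / sig)

  # posterior bath: Gaussian decay in the distance from the Pmap bounding box
  rng <- lapply(mm, function(a) range(a[pmap]))
  d_box <- sqrt(pmax(rng$z[1] - mm$z, mm$z - rng$z[2], 0)^2 +
                pmax(rng$y[1] - mm$y, mm$y - rng$y[2], 0)^2 +
                pmax(rng$x[1] - mm$x, mm$x - rng$x[2], 0)^2)
  bath <- exp(-d_box^2 / (2 * spec$spill_sigma^2))

  body <- spec$body_bath_amp * rx *
    exp(-d_cen^2 / (2 * spec$body_bath_sigma^2))

  # the three fields combine as a voxelwise max: the optimizer shapes the
  # total dose, so the bath does not stack on top of the target plateau
  field <- pmax(base, spec$posterior_spill * rx * bath + body)
  # conformity: the optimizer never lets near-prescription dose sit outside
  # the target, so cap the out-of-PTV field at 98% of prescription
  field[!ptv] <- pmin(field[!ptv], 0.98 * rx)
  noise <- with_seed(spec$seed,
                     array(stats::rnorm(prod(g$shape), 0, spec$noise_sd),
                           g$shape))
  initial <- pmax(field + noise, 0)

  atten_shape <- bath
  atten_shape[ptv] <- 0   # never touch PTV voxels
  m0 <- mean(initial[pmap])
  m_red <- mean((atten_shape * initial)[pmap])
  r <- if (spec$pmap_reduction_target == 0 || m_red == 0) 0 else
    spec$pmap_reduction_target * m0 / m_red
  achievable <- r <= 1
  r <- min(r, 1)
  optimized <- initial * (1 - r * atten_shape)
  achieved <- if (m0 > 0) (m0 - mean(optimized[pmap])) / m0 else 0

  list(initial = dose_grid(g, initial),
       optimized = dose_grid(g, optimized),
       achieved_reduction = achieved,
       achievable = achievable)
}

#' Default synthetic APT outcome model
#'
#' The logistic model used to draw APT outcomes and predicted probabilities
#' in synthetic cohorts. The Pmap mean BED dose carries the dominant weight;
#' clinical covariates (smoking, COPD, MEVS, stage) carry enough weight that
#' patients with a low Pmap dose can still exceed the 8% probability
#' threshold, reproducing the structure of the low-dose cohort.
#'
#' @return A `logistic_surrogate` [risk_model()].
#' @export
default_outcome_model <- function() {
  w <- c(dmean_pmap_bed = 0.12, dmean_2lungs = 0.08, v30_2lungs = 0.03,
         smoking_status = 1.0, mevs = -0.03, copd = 0.8, v10_lungh = 0.01,
         ajcc_stage = 0.5, v5_lungh = 0.005, dmean_lungh = 0.02,
         v40_heart = 0.04)
  risk_model("logistic_surrogate", weights = w, intercept = -6.0)
}

sample_clinical <- function(n) {
  data.frame(
    smoking_status = stats::rbinom(n, 1, 0.6),
    copd = stats::rbinom(n, 1, 0.3),
    mevs = pmin(150, pmax(20, stats::rnorm(n, 70, 15))),
    ajcc_stage = sample(0:2, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  )
}

#' Simulate a feature-level cohort
#'
#' Samples the 11-feature risk vectors directly from marginal distributions
#' (no dose painting) and draws a binary APT outcome from a known logistic
#' model — the fast generator used for parameter-recovery studies of
#' [fit_surrogate()]. The Pmap mean BED dose is drawn from a two-component
#' mixture mirroring a high-dose and a low-dose patient stratum.
#'
#' @param n Number of patients (>= 1).
#' @param model A logistic [risk_model()] supplying the outcome weights.
#' @param seed RNG seed.
#' @return Data frame with the 11 feature columns, `prob_apt` (the
#'   generative probability) and the binary `apt` outcome.
#' @export
simulate_feature_cohort <- function(n, model = default_outcome_model(),
                                    seed = 1) {
  if (n < 1) stop("'n' must be >= 1")
  stopifnot(inherits(model, "risk_model"), model$kind != "threshold_only")
  with_seed(seed, {
    cl <- sample_clinical(n)
    stratum <- stats::rbinom(n, 1, 0.55)
    feats <- data.frame(
      dmean_pmap_bed = pmax(1, ifelse(stratum == 1,
                                      stats::rnorm(n, 40.4, 4.4),
                                      stats::rnorm(n, 14.6, 4.0))),
      dmean_2lungs = pmax(2, stats::rnorm(n, 15, 2.5)),
      v30_2lungs = pmin(100, pmax(0, stats::rnorm(n, 15, 3))),
      smoking_status = cl$smoking_status,
      mevs = cl$mevs,
      copd = cl$copd,
      v10_lungh = pmin(100, pmax(0, stats::rnorm(n, 56, 8))),
      ajcc_stage = cl$ajcc_stage,
      v5_lungh = pmin(100, pmax(0, stats::rnorm(n, 65, 8))),
      dmean_lungh = pmax(1, stats::rnorm(n, 21, 3)),
      v40_heart = pmax(0, stats::rnorm(n, 4, 2))
    )
    p <- predict_prob_apt(feats, model)
    feats$prob_apt <- p
    feats$apt <- stats::rbinom(n, 1, p)
    feats
  })
}

# Per-patient anatomy: whole-anatomy integer shift plus an independent PTV
# jitter (posterior-biased in y) and PTV radius draw. The independent PTV
# motion is what spreads the PTV-Pmap overlap (Dice) across patients.
jitter_phantom <- function(base, shift, ptv_shift, ptv_radius) {
  mv <- function(c3) c3 + shift
  phantom_spec(shape = base$geometry$shape, spacing = base$geometry$spacing,
               origin = base$geometry$origin,
               lungh_center = mv(base$lungh_center),
               lungh_radii = base$lungh_radii,
               lungc_center = mv(base$lungc_center),
               lungc_radii = base$lungc_radii,
               heart_center = mv(base$heart_center),
               heart_radii = base$heart_radii,
               cord_center_yx = base$cord_center_yx + shift[2:3],
               cord_radius = base$cord_radius,
               ptv_center = mv(base$ptv_center) + ptv_shift,
               ptv_radius = ptv_radius,
               pmap_box = list(z = base$pmap_box$z + shift[1],
                               y = base$pmap_box$y + shift[2],
                               x = base$pmap_box$x + shift[3]))
}

#' Simulate a full imaging cohort
#'
#' The end-to-end generator: per patient it jitters the phantom anatomy,
#' paints a paired initial/optimized plan with patient-specific posterior
#' spill and reduction target, computes the full DVH metric panel for both
#' plans, predicts APT probabilities from each plan's dosimetry with the
#' outcome model, draws the APT outcome from the initial plan's generative
#' probability, adjudicates optimization success, and assigns the analysis
#' cohort. Deterministic given `seed` (per-patient sub-seeds are drawn
#' hierarchically from the master seed).
#'
#' @param n Number of patients (>= 1).
#' @param base_phantom A [phantom_spec()] the per-patient anatomy is
#'   jittered from.
#' @param outcome_model Logistic [risk_model()] for probabilities/outcomes.
#' @param constraints A [constraint_set()] for success adjudication.
#' @param spill_range Per-patient posterior spill drawn uniformly from this
#'   range; controls the spread of initial Pmap mean doses across the
#'   high/low-dose strata.
#' @param reduction_range Per-patient Pmap reduction target range.
#' @param noise_sd Painter voxel noise in Gy.
#' @param seed Master seed.
#' @return Data frame, one row per patient: clinical features, the metric
#'   panel of both plans (`*_ini` / `*_opt` columns), `dice_ptv_pmap`,
#'   probabilities, `apt` outcome, `success`, `success_reasons` and
#'   `cohort`.
#' @export
simulate_cohort <- function(n, base_phantom = phantom_spec(),
                            outcome_model = default_outcome_model(),
                            constraints = constraint_set(),
                            spill_range = c(0.05, 0.45),
                            reduction_range = c(0.10, 0.45),
                            noise_sd = 0.5, seed = 1) {
  if (n < 1) stop("'n' must be >= 1")
  sub <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    clinical = sample_clinical(n),
    spill = stats::runif(n, spill_range[1], spill_range[2]),
    target = stats::runif(n, reduction_range[1], reduction_range[2]),
    rx66 = stats::rbinom(n, 1, 0.5)
  ))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    geom_jit <- with_seed(sub$seeds[i], list(
      shift = sample(-2:2, 3, replace = TRUE),
      ptv_shift = c(sample(-1:1, 1), sample(-1:4, 1), sample(-1:1, 1)),
      ptv_radius = base_phantom$ptv_radius + sample(-1:1, 1)))
    ps <- jitter_phantom(base_phantom, geom_jit$shift, geom_jit$ptv_shift,
                         geom_jit$ptv_radius)
    ss <- generate_phantom(ps)
    fx <- if (sub$rx66[i] == 1) fractionation(66, 33) else fractionation(60, 30)
    pp <- paint_plan_pair(ss, plan_painter_spec(
      fx = fx, posterior_spill = sub$spill[i],
      pmap_reduction_target = sub$target[i], noise_sd = noise_sd,
      seed = sub$seeds[i]))
    m_ini <- compute_plan_metrics(pp$initial, ss, fx)
    m_opt <- compute_plan_metrics(pp$optimized, ss, fx)
    feats <- function(m) data.frame(
      dmean_pmap_bed = m[["pmap_dmean_bed"]],
      dmean_2lungs = m[["two_lungs_dmean"]],
      v30_2lungs = m[["two_lungs_v30"]],
      smoking_status = sub$clinical$smoking_status[i],
      mevs = sub$clinical$mevs[i],
      copd = sub$clinical$copd[i],
      v10_lungh = m[["lungh_v10"]],
      ajcc_stage = sub$clinical$ajcc_stage[i],
      v5_lungh = m[["lungh_v5"]],
      dmean_lungh = m[["lungh_dmean"]],
      v40_heart = m[["heart_v40"]]
    )
    p_ini <- predict_prob_apt(feats(m_ini), outcome_model)
    p_opt <- predict_prob_apt(feats(m_opt), outcome_model)
    adj <- adjudicate_success(m_ini, m_opt, constraints)
    apt <- with_seed(sub$seeds[i] + 1L, stats::rbinom(1, 1, p_ini))
    ini <- as.list(unclass(m_ini))
    names(ini) <- paste0(names(ini), "_ini")
    opt <- as.list(unclass(m_opt))
    names(opt) <- paste0(names(opt), "_opt")
    rows[[i]] <- cbind(
      data.frame(id = i, sub$clinical[i, , drop = FALSE],
                 prescription_dose = fx$prescription_dose,
                 n_fractions = fx$n_fractions,
                 posterior_spill = sub$spill[i],
                 reduction_target = sub$target[i], row.names = NULL),
      as.data.frame(ini), as.data.frame(opt),
      data.frame(dice_ptv_pmap = dice(ss$masks$PTV, ss$masks$Pmap),
                 prob_initial = p_ini, prob_optimized = p_opt, apt = apt,
                 success = adj$success,
                 success_reasons = paste(adj$reasons, collapse = "; ")))
  }
  out <- do.call(rbind, rows)
  out$cohort <- assign_cohort(out$prob_initial, out$pmap_dmean_bed_ini,
                              out$success,
                              prob_threshold = outcome_model$prob_threshold,
                              dmean_threshold = outcome_model$dmean_threshold)
  out
}
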