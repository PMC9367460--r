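# Shared fixtures and independent brute-force oracles. The oracles iterate
# over explicit voxel lists / all pairs and never call the package's own
# metric code paths.

rand_geometry <- function(n, spacing = c(4, 4, 4), origin = c(0, 0, 0)) {
  grid_geometry(rep(n, 3), spacing, origin)
}

rand_mask <- function(g, p = 0.2) {
  binary_mask(g, array(stats::runif(prod(g$shape)) < p, g$shape))
}

nonempty_rand_mask <- function(g, p = 0.2) {
  m <- rand_mask(g, p)
  if (mask_voxel_count(m) == 0L) {
    v <- m$values
    v[1] <- TRUE
    m <- binary_mask(g, v)
  }
  m
}

rand_dose <- function(g, max_gy = 70) {
  dose_grid(g, array(stats::runif(prod(g$shape), 0, max_gy), g$shape))
}

# Brute-force loop over the in-mask voxel list.
oracle_vx <- function(d, m, x) {
  doses <- d$values[which(m$values)]
  hits <- 0L
  for (v in doses) if (v >= x) hits <- hits + 1L
  100 * hits / length(doses)
}

oracle_dose_stats <- function(d, m) {
  doses <- d$values[which(m$values)]
  s <- 0
  mx <- -Inf
  for (v in doses) {
    s <- s + v
    if (v > mx) mx <- v
  }
  c(dmean = s / length(doses), dmax = mx)
}

# Sort-based quantile oracle for Dq%: dose received by at least q% of the
# volume = the (1 - q/100) order statistic from above.
oracle_dq <- function(d, m, q) {
  doses <- sort(d$values[which(m$values)], decreasing = TRUE)
  k <- ceiling(q / 100 * length(doses))
  doses[max(1L, k)]
}

oracle_dice <- function(a, b) {
  ia <- which(a$values)
  ib <- which(b$values)
  inter <- 0L
  for (i in ia) if (b$values[i]) inter <- inter + 1L
  if (length(ia) + length(ib) == 0L) return(0)
  2 * inter / (length(ia) + length(ib))
}

# All-pairs Mann-Whitney AUC with half credit for ties; positive class has
# label TRUE and is expected to carry the HIGHER score.
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Brute-force Youden maximisation over all candidate cutoffs (midpoints of
# adjacent distinct scores plus outer sentinels); classification is
# score >= cutoff -> positive.
oracle_best_youden <- function(scores, positive) {
  s <- sort(unique(scores))
  cand <- c(min(s) - 1, (s[-1] + s[-length(s)]) / 2, max(s) + 1)
  if (length(s) == 1L) cand <- c(s - 1, s + 1)
  best <- -Inf
  for (cut in cand) {
    pred <- scores >= cut
    sens <- sum(pred & positive) / sum(positive)
    spec <- sum(!pred & !positive) / sum(!positive)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Half-scale phantom for fast unit tests (32^3 at 4 mm).
small_phantom_spec <- function() {
  phantom_spec(shape = c(32, 32, 32), spacing = c(4, 4, 4),
               lungh_center = c(16, 16, 10), lungh_radii = c(12, 9, 5.5),
               lungc_center = c(16, 16, 23), lungc_radii = c(12, 9, 5.5),
               heart_center = c(17, 18, 19), heart_radii = c(5, 4.5, 4.5),
               cord_center_yx = c(27, 16), cord_radius = 1,
               ptv_center = c(16, 17, 10), ptv_radius = 3,
               pmap_box = list(z = c(13, 19), y = c(21, 25), x = c(6, 12)))
}

fig3_patient1 <- function() {
  list(initial = plan_metrics_from_values(ptv95 = 96.4, pmap_dmean_bed = 36.5),
       optimized = plan_metrics_from_values(ptv95 = 97.7,
                                            pmap_dmean_bed = 24.8))
}

fig3_patient6 <- function() {
  list(initial = plan_metrics_from_values(ptv95 = 93.6, pmap_dmean_bed = 60.2),
       optimized = plan_metrics_from_values(ptv95 = 68.3,
                                            pmap_dmean_bed = 44.2))
}

strong_recovery_model <- function() {
  # generative weights for recovery studies: standardized magnitudes ~2.2-2.7
  # so +/-15% relative spans >= 5 coefficient SEs at n = 2000
  w <- c(dmean_pmap_bed = 0.20, dmean_2lungs = 0.90, v30_2lungs = 0.80,
         smoking_status = 4.5, mevs = -0.15, copd = 5.0, v10_lungh = 0.30,
         ajcc_stage = 3.3, v5_lungh = -0.28, dmean_lungh = 0.75,
         v40_heart = 1.10)
  risk_model("logistic_surrogate", weights = w, intercept = -45.8)
}

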