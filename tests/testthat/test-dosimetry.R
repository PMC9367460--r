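uniform_dose <- function(g, gy) dose_grid(g, array(gy, g$shape))
full_mask <- function(g) binary_mask(g, array(TRUE, g$shape))

test_that("fractionation enforces dose-per-fraction bounds", {
  fx <- fractionation(66, 33)
  expect_equal(fx$prescription_dose / fx$n_fractions, 2)
  expect_error(fractionation(0, 30), "> 0")
  expect_error(fractionation(60, 0), "positive")
  expect_error(fractionation(500, 10), "20 Gy")
})

test_that("BED conversion follows the linear-quadratic closed form", {
  g <- rand_geometry(4)
  fx <- fractionation(60, 30)
  # 60 Gy in 30 fractions, alpha/beta 10: 60 * (1 + 2/10) = 72
  expect_equal(to_bed(uniform_dose(g, 60), fx, 10)$values,
               array(72, g$shape))
  # zero dose stays zero
  expect_equal(to_bed(uniform_dose(g, 0), fx, 3)$values, array(0, g$shape))
  # large alpha/beta limit: BED -> physical
  set.seed(5)
  d <- rand_dose(g)
  bed_inf <- to_bed(d, fx, 1e9)
  expect_lt(max(abs(bed_inf$values - d$values) / pmax(d$values, 1e-300)),
            1e-6)
  expect_equal(bed_inf$dose_kind, "BED")
  expect_error(to_bed(d, fx, 0), "> 0")
  expect_error(to_bed(bed_inf, fx, 3), "physical")
})

test_that("BED is monotone in dose and never below physical dose", {
  g <- rand_geometry(6)
  fx <- fractionation(66, 33)
  for (s in 1:5) {
    set.seed(s)
    d1 <- rand_dose(g, 40)
    d2 <- dose_grid(g, d1$values + array(stats::runif(prod(g$shape), 0, 20),
                                         g$shape))
    b1 <- to_bed(d1, fx, 3)$values
    b2 <- to_bed(d2, fx, 3)$values
    expect_true(all(b2 >= b1))
    expect_true(all(b1 >= d1$values))
  }
})

test_that("cumulative DVH matches direct voxel counting", {
  g <- rand_geometry(4)
  expect_error(cumulative_dvh(uniform_dose(g, 10),
                              binary_mask(g, array(FALSE, g$shape))),
               "empty structure")

  # uniform 10 Gy: fraction 1 at edges <= 10, 0 above
  curve <- cumulative_dvh(uniform_dose(g, 10), full_mask(g))
  expect_equal(curve$cum_volume_fraction[curve$dose_edges <= 10],
               rep(1, sum(curve$dose_edges <= 10)))
  expect_equal(curve$cum_volume_fraction[curve$dose_edges > 10],
               rep(0, sum(curve$dose_edges > 10)))

  # two voxels at 0 and 10 Gy: fraction 0.5 at edge 5
  g2 <- grid_geometry(c(1, 1, 2), c(1, 1, 1))
  d2 <- dose_grid(g2, array(c(0, 10), c(1, 1, 2)))
  c2 <- cumulative_dvh(d2, full_mask(g2))
  expect_equal(c2$cum_volume_fraction[c2$dose_edges == 5], 0.5)
  expect_equal(c2$cum_volume_fraction[1], 1)

  # random grid: every queried edge equals a voxel-loop count
  g3 <- rand_geometry(16)
  set.seed(9)
  d3 <- rand_dose(g3, 30)
  m3 <- nonempty_rand_mask(g3, 0.3)
  c3 <- cumulative_dvh(d3, m3, bin_width = 1)
  doses <- d3$values[which(m3$values)]
  for (k in seq_along(c3$dose_edges)) {
    hits <- 0L
    for (v in doses) if (v >= c3$dose_edges[k]) hits <- hits + 1L
    expect_equal(c3$cum_volume_fraction[k], hits / length(doses))
  }
  expect_true(all(diff(c3$cum_volume_fraction) <= 0))
})

test_that("Vx uses an exact inclusive voxel count", {
  g <- rand_geometry(12)
  set.seed(3)
  d <- rand_dose(g, 50)
  m <- nonempty_rand_mask(g, 0.25)
  expect_equal(v_at_dose(d, m, 0), 100)
  expect_equal(v_at_dose(d, m, max(d$values[m$values]) + 1), 0)
  for (x in c(5, 20, 35)) expect_equal(v_at_dose(d, m, x), oracle_vx(d, m, x))
  # ties at the threshold count as covered
  g1 <- grid_geometry(c(1, 1, 4), c(1, 1, 1))
  d1 <- dose_grid(g1, array(c(10, 10, 5, 20), c(1, 1, 4)))
  expect_equal(v_at_dose(d1, full_mask(g1), 10), 75)
})

test_that("Dq% interpolates the DVH and agrees with a sort-based oracle", {
  g <- rand_geometry(4)
  curve <- cumulative_dvh(uniform_dose(g, 10), full_mask(g))
  expect_equal(d_at_volume(curve, 95), d_at_volume(curve, 5))
  expect_lt(abs(d_at_volume(curve, 95) - 10), 0.1 + 1e-9)

  bin <- 0.1
  for (s in 1:5) {
    g2 <- rand_geometry(16)
    set.seed(s)
    d <- rand_dose(g2, 60)
    m <- nonempty_rand_mask(g2, 0.3)
    curve <- cumulative_dvh(d, m, bin_width = bin)
    for (q in c(5, 50, 95, 100)) {
      expect_lt(abs(d_at_volume(curve, q) - oracle_dq(d, m, q)), bin + 1e-9)
    }
    expect_gte(d_at_volume(curve, 5), d_at_volume(curve, 95))  # monotone in q
  }
  expect_error(d_at_volume(curve, 0), "0, 100")
  bad <- structure(list(dose_edges = c(0, 1, 0.5),
                        cum_volume_fraction = c(1, 0.5, 0.2)),
                   class = "dvh_curve")
  expect_error(d_at_volume(bad, 50), "malformed")
})

test_that("dose statistics match the brute-force oracle", {
  g <- grid_geometry(c(1, 1, 2), c(1, 1, 1))
  d <- dose_grid(g, array(c(0, 20), c(1, 1, 2)))
  expect_equal(dose_stats(d, full_mask(g)), c(dmean = 10, dmax = 20))
  for (s in 1:5) {
    g2 <- rand_geometry(12)
    set.seed(s + 20)
    d2 <- rand_dose(g2)
    m2 <- nonempty_rand_mask(g2)
    o <- oracle_dose_stats(d2, m2)
    got <- dose_stats(d2, m2)
    expect_equal(got[["dmax"]], o[["dmax"]])
    expect_lt(abs(got[["dmean"]] - o[["dmean"]]), 1e-9)
    expect_lte(min(d2$values[m2$values]), got[["dmean"]])
    expect_lte(got[["dmean"]], got[["dmax"]])
    expect_equal(v_at_dose(d2, m2, got[["dmax"]] + 1e-6), 0)
  }
})

test_that("PTV95 is coverage at 95% of prescription", {
  g <- rand_geometry(6)
  fx <- fractionation(66, 33)
  ptv <- full_mask(g)
  expect_equal(ptv_coverage(uniform_dose(g, 66), ptv, fx), 100)
  expect_equal(ptv_coverage(uniform_dose(g, 0.9 * 66), ptv, fx), 0)
  ss <- generate_phantom(small_phantom_spec())
  pp <- paint_plan_pair(ss, plan_painter_spec(fx = fx, seed = 4))
  expect_equal(ptv_coverage(pp$initial, ss$masks$PTV, fx),
               oracle_vx(pp$initial, ss$masks$PTV, 0.95 * 66))
})

test_that("the plan-metric panel agrees field by field with its parts", {
  ss <- generate_phantom(small_phantom_spec())
  fx <- fractionation(66, 33)
  pp <- paint_plan_pair(ss, plan_painter_spec(fx = fx, seed = 2))
  d <- pp$initial
  m <- compute_plan_metrics(d, ss, fx)

  expect_equal(m[["ptv95"]], ptv_coverage(d, ss$masks$PTV, fx))
  expect_equal(m[["lungh_v20"]], v_at_dose(d, ss$masks$LungH, 20))
  expect_equal(m[["lungc_v5"]], v_at_dose(d, ss$masks$LungC, 5))
  expect_equal(m[["two_lungs_v30"]], v_at_dose(d, ss$masks$`2Lungs`, 30))
  expect_equal(m[["heart_v40"]], v_at_dose(d, ss$masks$Heart, 40))
  expect_equal(m[["spinalcord_dmax"]],
               dose_stats(d, ss$masks$SpinalCord)[["dmax"]])
  expect_equal(m[["lungh_dmean"]], dose_stats(d, ss$masks$LungH)[["dmean"]])
  # Pmap mean is on the BED grid with alpha/beta 3
  bed <- to_bed(d, fx, 3)
  expect_equal(m[["pmap_dmean_bed"]],
               dose_stats(bed, ss$masks$Pmap)[["dmean"]])
  expect_gt(m[["pmap_dmean_bed"]],
            dose_stats(d, ss$masks$Pmap)[["dmean"]])
  expect_equal(m[["ic"]], conformity_index(d, ss$masks$PTV, fx))
  expect_equal(m[["hiv"]], heterogeneity_index(d, ss$masks$PTV))
  expect_true(all(!is.na(unclass(m))))

  # Vx non-increasing in x across the panel
  expect_true(m[["lungh_v5"]] >= m[["lungh_v10"]])
  expect_true(m[["lungh_v10"]] >= m[["lungh_v13"]])
  expect_true(m[["lungh_v13"]] >= m[["lungh_v20"]])
  expect_true(m[["lungh_v20"]] >= m[["lungh_v30"]])
})

test_that("a zero dose grid yields a zeroed panel", {
  ss <- generate_phantom(small_phantom_spec())
  fx <- fractionation(66, 33)
  expect_warning(
    m <- compute_plan_metrics(dose_grid(ss$geometry,
                                        array(0, ss$geometry$shape)), ss, fx),
    "heterogeneity")
  expect_true(is.na(m[["hiv"]]))
  expect_equal(m[["ptv95"]], 0)
  expect_equal(m[["lungh_v5"]], 0)
  expect_equal(m[["two_lungs_v13"]], 0)
  expect_equal(m[["lungh_dmean"]], 0)
  expect_equal(m[["spinalcord_dmax"]], 0)
  expect_equal(m[["pmap_dmean_bed"]], 0)
  expect_equal(m[["ic"]], 0)
})

test_that("plan metrics can be built from printed report values", {
  m <- plan_metrics_from_values(ptv95 = 96.4, pmap_dmean_bed = 36.5)
  expect_equal(m[["ptv95"]], 96.4)
  expect_true(is.na(m[["lungh_v5"]]))
  expect_error(plan_metrics_from_values(nonsense = 1), "unknown metric")
})
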