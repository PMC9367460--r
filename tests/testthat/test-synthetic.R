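test_that("phantom generation is deterministic and validated", {
  s1 <- generate_phantom(small_phantom_spec())
  s2 <- generate_phantom(small_phantom_spec())
  for (nm in names(s1$masks))
    expect_identical(s1$masks[[nm]]$values, s2$masks[[nm]]$values)

  expect_error(phantom_spec(ptv_radius = 0), "> 0")

  # Pmap centroid sits in the posterior-right octant
  ss <- generate_phantom()
  idx <- pmapdose:::index_grids(ss$geometry$shape)
  sel <- ss$masks$Pmap$values
  expect_gt(mean(idx$y[sel]), ss$geometry$shape[2] / 2)
  expect_lt(mean(idx$x[sel]), ss$geometry$shape[3] / 2)

  # a PTV pushed outside the lung is refused
  bad <- small_phantom_spec()
  bad$ptv_center <- c(16, 17, 20)
  expect_error(generate_phantom(bad), "homolateral lung")
})

test_that("plan painting is deterministic and respects the PTV", {
  ss <- generate_phantom(small_phantom_spec())
  spec <- plan_painter_spec(seed = 7)
  a <- paint_plan_pair(ss, spec)
  b <- paint_plan_pair(ss, spec)
  expect_identical(a$initial$values, b$initial$values)
  expect_identical(a$optimized$values, b$optimized$values)

  # PTV voxels are untouched by the optimization
  ptv <- ss$masks$PTV$values
  expect_identical(a$initial$values[ptv], a$optimized$values[ptv])
})

test_that("zero reduction target leaves the Pmap mean unchanged", {
  ss <- generate_phantom(small_phantom_spec())
  pp <- paint_plan_pair(ss, plan_painter_spec(pmap_reduction_target = 0,
                                              seed = 5))
  pm <- ss$masks$Pmap$values
  m_ini <- mean(pp$initial$values[pm])
  m_opt <- mean(pp$optimized$values[pm])
  expect_lt(abs(m_opt - m_ini) / m_ini, 0.02)
  expect_error(plan_painter_spec(pmap_reduction_target = 1), "\\[0, 1\\)")
})

test_that("the painter hits a 30% reduction without losing coverage", {
  ss <- generate_phantom()
  fx <- fractionation(66, 33)
  pp <- paint_plan_pair(ss, plan_painter_spec(fx = fx,
                                              pmap_reduction_target = 0.30,
                                              seed = 7))
  expect_true(pp$achievable)
  expect_lt(abs(pp$achieved_reduction - 0.30), 0.05)
  ptv95_ini <- ptv_coverage(pp$initial, ss$masks$PTV, fx)
  ptv95_opt <- ptv_coverage(pp$optimized, ss$masks$PTV, fx)
  expect_lt(abs(ptv95_ini - ptv95_opt), 1.0)
})

test_that("increasing posterior spill strictly raises the Pmap mean dose", {
  ss <- generate_phantom(small_phantom_spec())
  means <- vapply(c(0, 0.1, 0.2, 0.3, 0.45), function(spill) {
    pp <- paint_plan_pair(ss, plan_painter_spec(posterior_spill = spill,
                                                seed = 4))
    mean(pp$initial$values[ss$masks$Pmap$values])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("feature cohorts are deterministic with coherent probabilities", {
  a <- simulate_feature_cohort(50, seed = 21)
  b <- simulate_feature_cohort(50, seed = 21)
  expect_identical(a, b)
  expect_true(all(a$prob_apt >= 0 & a$prob_apt <= 1))
  expect_true(all(a$apt %in% c(0, 1)))
  expect_error(simulate_feature_cohort(0), ">= 1")
})

test_that("full cohorts are deterministic and exercise every branch", {
  expect_error(simulate_cohort(0), ">= 1")
  small_a <- simulate_cohort(2, seed = 33)
  small_b <- simulate_cohort(2, seed = 33)
  expect_identical(small_a, small_b)

  coh <- simulate_cohort(60, seed = 11)
  expect_setequal(unique(coh$cohort), c("1", "2", "3", "excluded"))
  expect_true(all(coh$success[coh$cohort == "1"]))
  expect_false(any(coh$success[coh$cohort == "2"]))
  expect_true(all(coh$pmap_dmean_bed_ini[coh$cohort %in% c("1", "2")] >=
                    30.3))
  expect_true(all(coh$pmap_dmean_bed_ini[coh$cohort == "3"] < 30.3))
  expect_true(all(coh$prob_initial[coh$cohort == "excluded"] < 0.08))
  expect_true(all(abs(coh$ptv95_ini - coh$ptv95_opt) < 1.0))

  # every failure carries at least one reason
  expect_true(all(nchar(coh$success_reasons[!coh$success]) > 0))

  # reclassification equals a per-record threshold audit
  incl <- coh$cohort != "excluded"
  rs <- reclassification_summary(coh$prob_initial[incl],
                                 coh$prob_optimized[incl])
  audit_h2l <- 0L
  for (i in which(incl)) {
    if (coh$prob_initial[i] >= 0.08 && coh$prob_optimized[i] < 0.08)
      audit_h2l <- audit_h2l + 1L
  }
  expect_equal(rs$high_to_low, audit_h2l)
})
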