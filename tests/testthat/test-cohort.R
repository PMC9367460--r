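test_that("cohort assignment matches the rules on the full truth table", {
  # all 2x2x2 combinations of (prob >= 8%, dmean >= 30.3, success)
  cases <- expand.grid(prob = c(0.05, 0.94), dmean = c(14.6, 36.6),
                       success = c(TRUE, FALSE))
  expected <- with(cases, ifelse(prob < 0.08, "excluded",
                          ifelse(dmean >= 30.3, ifelse(success, "1", "2"),
                                 "3")))
  got <- assign_cohort(cases$prob, cases$dmean, cases$success)
  expect_equal(got, expected)
  # the partition covers every case
  expect_true(all(got %in% c("1", "2", "3", "excluded")))

  # inclusive boundaries: exactly 8% and exactly 30.3 Gy are high
  expect_equal(assign_cohort(0.08, 30.3, TRUE), "1")
  expect_equal(assign_cohort(0.08, 30.3 - 1e-9, FALSE), "3")
  expect_error(assign_cohort(NA, 30, TRUE), "missing")
})

test_that("success adjudication reproduces the worked patient examples", {
  p1 <- fig3_patient1()
  adj1 <- adjudicate_success(p1$initial, p1$optimized)
  expect_true(adj1$success)
  expect_length(adj1$reasons, 0)

  p6 <- fig3_patient6()
  adj6 <- adjudicate_success(p6$initial, p6$optimized)
  expect_false(adj6$success)
  expect_true(any(grepl("coverage", adj6$reasons)))
  expect_true(any(grepl("Pmap", adj6$reasons)))
})

test_that("the low-dose cohort uses the 20% relative-reduction rule", {
  ini <- plan_metrics_from_values(ptv95 = 95.8, pmap_dmean_bed = 14.6)
  opt <- plan_metrics_from_values(ptv95 = 95.8, pmap_dmean_bed = 10.3)
  adj <- adjudicate_success(ini, opt)   # 29.5% drop, coverage unchanged
  expect_true(adj$success)

  small_drop <- plan_metrics_from_values(ptv95 = 95.8,
                                         pmap_dmean_bed = 12.5)  # 14.4%
  adj2 <- adjudicate_success(ini, small_drop)
  expect_false(adj2$success)
  expect_match(adj2$reasons, "reduction", all = FALSE)
})

test_that("organ-at-risk constraints fail with named reasons", {
  ini <- plan_metrics_from_values(ptv95 = 96, pmap_dmean_bed = 40,
                                  two_lungs_v20 = 30, spinalcord_dmax = 40,
                                  heart_v40 = 10)
  opt <- plan_metrics_from_values(ptv95 = 96, pmap_dmean_bed = 25,
                                  two_lungs_v20 = 40, spinalcord_dmax = 40,
                                  heart_v40 = 10)
  adj <- adjudicate_success(ini, opt)
  expect_false(adj$success)
  expect_match(adj$reasons, "two_lungs_v20", all = FALSE)

  # a custom constraint set can relax the bound
  loose <- constraint_set(data.frame(metric = "two_lungs_v20", bound = 45,
                                     direction = "le"))
  expect_true(adjudicate_success(ini, opt, loose)$success)
  expect_error(constraint_set(data.frame(metric = "nope", bound = 1,
                                         direction = "le")), "unknown")
})

test_that("failure always carries reasons and success is dose-monotone", {
  set.seed(12)
  for (i in 1:40) {
    d_ini <- stats::runif(1, 10, 60)
    d_opt <- stats::runif(1, 5, 60)
    cov_ini <- stats::runif(1, 90, 99)
    cov_opt <- stats::runif(1, 60, 99)
    ini <- plan_metrics_from_values(ptv95 = cov_ini, pmap_dmean_bed = d_ini)
    opt <- plan_metrics_from_values(ptv95 = cov_opt, pmap_dmean_bed = d_opt)
    adj <- adjudicate_success(ini, opt)
    if (!adj$success) expect_gt(length(adj$reasons), 0)
    # lowering the optimized Pmap dose can never break a success
    lower <- plan_metrics_from_values(ptv95 = cov_opt,
                                      pmap_dmean_bed = d_opt * 0.5)
    if (adj$success)
      expect_true(adjudicate_success(ini, lower)$success)
  }
})

test_that("plan-set comparison picks tests by normality and reports CIs", {
  make_arm <- function(vals) lapply(vals, function(v)
    plan_metrics_from_values(ptv95 = v, pmap_dmean_bed = v / 2))
  identical_rows <- compare_plan_sets(make_arm(c(94, 95, 96, 97, 95.5)),
                                      make_arm(c(94, 95, 96, 97, 95.5)))
  expect_gte(min(identical_rows$p_value), 0.9)
  expect_true(all(identical_rows$ci_lo_initial <=
                    identical_rows$mean_initial))
  expect_true(all(identical_rows$mean_initial <=
                    identical_rows$ci_hi_initial))

  set.seed(31)
  a <- stats::rnorm(50, 50, 2)
  b <- stats::rnorm(50, 44, 2)       # 3 sigma shift
  shifted <- compare_plan_sets(make_arm(a), make_arm(b))
  row <- shifted[shifted$metric == "ptv95", ]
  expect_lt(row$p_value, 0.001)
  expect_equal(row$test_used, "t")

  set.seed(32)
  h1 <- abs(stats::rcauchy(40, 50, 4))
  h2 <- abs(stats::rcauchy(40, 50, 4))
  heavy <- compare_plan_sets(make_arm(h1), make_arm(h2))
  expect_equal(heavy$test_used[heavy$metric == "ptv95"], "mann_whitney")

  expect_error(compare_plan_sets(make_arm(c(1, 2)), make_arm(c(1, 2, 3))),
               "at least 3")
})

test_that("reclassification counts, conservation and paired tests hold", {
  same <- reclassification_summary(c(0.5, 0.02, 0.9), c(0.5, 0.02, 0.9))
  expect_equal(same$high_to_low, 0)
  expect_equal(same$p_mcnemar_exact, 1)
  expect_equal(same$p_wilcoxon_paired, 1)

  # 24 records, exactly 8 high->low and 0 low->high: 33.3%
  p_ini <- rep(0.9, 24)
  p_opt <- c(rep(0.04, 8), rep(0.9, 16))
  rs <- reclassification_summary(p_ini, p_opt)
  expect_equal(rs$high_to_low, 8)
  expect_equal(rs$low_to_high, 0)
  expect_equal(rs$reclassified_fraction, 8 / 24)
  expect_equal(round(100 * rs$high_to_low_fraction, 1), 33.3)
  expect_lt(rs$p_mcnemar_exact, 0.01)

  # conservation on random paired probabilities
  set.seed(44)
  for (i in 1:10) {
    pi <- stats::runif(30)
    po <- stats::runif(30)
    r <- reclassification_summary(pi, po)
    expect_equal(sum(classify_by_prob(pi) == "high"),
                 r$stays_high + r$high_to_low)
    expect_equal(r$n, r$stays_high + r$stays_low + r$high_to_low +
                   r$low_to_high)
  }
  expect_error(reclassification_summary(numeric(0), numeric(0)), "empty")
})

test_that("ROC of Dice vs failure matches the pairwise oracle", {
  # perfectly separated: failures all carry higher Dice
  r <- roc_dice_vs_success(c(0.3, 0.4, 0.05, 0.1),
                           c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_gt(r$youden_cutoff, 0.1)
  expect_lt(r$youden_cutoff, 0.3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  set.seed(50)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    scores <- round(stats::runif(n), 2)    # rounding forces ties
    success <- stats::runif(n) < 0.5
    if (length(unique(success)) < 2) next
    r <- roc_dice_vs_success(scores, success)
    expect_equal(r$auc, oracle_auc(scores, positive = !success),
                 tolerance = 1e-12)
    # Youden at the reported cutoff equals the brute-force maximum
    pred_fail <- scores >= r$youden_cutoff
    j <- sum(pred_fail & !success) / sum(!success) +
      sum(!pred_fail & success) / sum(success) - 1
    expect_equal(j, oracle_best_youden(scores, positive = !success),
                 tolerance = 1e-9)
  }
  expect_error(roc_dice_vs_success(c(0.1, 0.2), c(TRUE, TRUE)),
               "both successful and unsuccessful")
})

test_that("AUC is invariant under monotone score transforms", {
  set.seed(60)
  scores <- stats::runif(40)
  success <- stats::runif(40) < 0.5
  r1 <- roc_dice_vs_success(scores, success)
  r2 <- roc_dice_vs_success(scores^3, success)
  expect_equal(r1$auc, r2$auc)
})
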