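#' Dose-constraint set for success adjudication
#'
#' Named upper/lower bounds on plan-metric fields, plus the PTV-coverage
#' rule used when adjudicating optimization success: the optimized plan must
#' keep `ptv95 >= min(ptv95_floor, initial ptv95 - ptv95_drop_tolerance)`,
#' so plans whose initial coverage already sat below the floor are judged
#' against their own baseline rather than an unreachable absolute floor.
#'
#' The default organ-at-risk bounds are standard lung-RT planning
#' constraints (both lungs V20 <= 35%, spinal cord Dmax <= 45 Gy, heart
#' V40 <= 30%); they are a conventional default, fully overridable.
#'
#' @param constraints Data frame with columns `metric` (a
#'   [plan_metric_names()] field), `bound` (numeric) and `direction`
#'   (`"le"` or `"ge"`).
#' @param ptv95_floor Coverage floor in percent (default 95).
#' @param ptv95_drop_tolerance Allowed coverage drop in percentage points
#'   (default 1).
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(constraints = default_oar_constraints(),
                           ptv95_floor = 95, ptv95_drop_tolerance = 1.0) {
  stopifnot(is.data.frame(constraints),
            all(c("metric", "bound", "direction") %in% names(constraints)))
  unknown <- setdiff(constraints$metric, plan_metric_names())
  if (length(unknown) > 0)
    stop("constraints name unknown metrics: ", paste(unknown, collapse = ", "))
  if (!all(constraints$direction %in% c("le", "ge")))
    stop("constraint direction must be 'le' or 'ge'")
  if (any(!is.finite(constraints$bound))) stop("constraint bounds must be finite")
  structure(list(constraints = constraints, ptv95_floor = ptv95_floor,
                 ptv95_drop_tolerance = ptv95_drop_tolerance),
            class = "constraint_set")
}

#' @rdname constraint_set
#' @export
default_oar_constraints <- function() {
  data.frame(
    metric = c("two_lungs_v20", "spinalcord_dmax", "heart_v40"),
    bound = c(35, 45, 30),
    direction = "le",
    stringsAsFactors = FALSE
  )
}

#' Assign a patient to an analysis cohort
#'
#' Patients with a predicted APT probability below the 8% threshold are
#' excluded. Among included patients, those whose initial Pmap mean BED dose
#' is at or above 30.3 Gy fall into Cohort 1 when the optimization succeeded
#' and Cohort 2 when it did not; those below 30.3 Gy form Cohort 3
#' regardless of success.
#'
#' @param prob_initial Predicted APT probability for the initial plan.
#' @param dmean_pmap_ini Initial Pmap mean BED dose in Gy.
#' @param success Logical, optimization success flag.
#' @param prob_threshold,dmean_threshold Decision thresholds.
#' @return Character vector over `"1"`, `"2"`, `"3"`, `"excluded"`.
#' @export
assign_cohort <- function(prob_initial, dmean_pmap_ini, success,
                          prob_threshold = 0.08, dmean_threshold = 30.3) {
  n <- max(length(prob_initial), length(dmean_pmap_ini), length(success))
  prob_initial <- rep_len(prob_initial, n)
  dmean_pmap_ini <- rep_len(dmean_pmap_ini, n)
  success <- rep_len(success, n)
  if (any(!is.finite(prob_initial)) || any(!is.finite(dmean_pmap_ini)))
    stop("missing or non-finite probability / dose input")
  if (any(is.na(success))) stop("missing success flag")
  out <- rep("excluded", n)
  incl <- prob_initial >= prob_threshold
  hi <- incl & dmean_pmap_ini >= dmean_threshold
  out[hi & success] <- "1"
  out[hi & !success] <- "2"
  out[incl & !hi] <- "3"
  out
}

coverage_maintained <- function(ptv95_ini, ptv95_opt, cs) {
  ptv95_opt >= min(cs$ptv95_floor, ptv95_ini - cs$ptv95_drop_tolerance)
}

#' Adjudicate optimization success for one patient
#'
#' Two rules, selected by the initial Pmap mean BED dose:
#' \itemize{
#'   \item High-dose rule (initial Dmean Pmap >= 30.3 Gy; Cohorts 1/2):
#'     success requires the optimized Pmap mean BED dose strictly below
#'     30.3 Gy, maintained PTV coverage, and all organ-at-risk constraints
#'     met on the optimized plan.
#'   \item Low-dose rule (initial Dmean Pmap < 30.3 Gy; Cohort 3): success
#'     requires a relative Pmap mean-dose reduction of at least 20% with
#'     maintained PTV coverage.
#' }
#'
#' @param metrics_initial,metrics_optimized `plan_metrics` for the paired
#'   plans.
#' @param constraints A [constraint_set()].
#' @param dmean_threshold Pmap BED threshold in Gy (default 30.3).
#' @param min_relative_reduction Cohort-3 relative reduction requirement
#'   (default 0.20).
#' @return List with `success` (logical) and `reasons` (character vector of
#'   every failed criterion; empty on success).
#' @export
adjudicate_success <- function(metrics_initial, metrics_optimized,
                               constraints = constraint_set(),
                               dmean_threshold = 30.3,
                               min_relative_reduction = 0.20) {
  stopifnot(inherits(metrics_initial, "plan_metrics"),
            inherits(metrics_optimized, "plan_metrics"),
            inherits(constraints, "constraint_set"))
  need <- c("ptv95", "pmap_dmean_bed")
  for (f in need) {
    if (is.na(metrics_initial[f]) || is.na(metrics_optimized[f]))
      stop("metric '", f, "' missing from plan metrics")
  }
  d_ini <- metrics_initial[["pmap_dmean_bed"]]
  d_opt <- metrics_optimized[["pmap_dmean_bed"]]
  reasons <- character(0)
  if (!coverage_maintained(metrics_initial[["ptv95"]],
                           metrics_optimized[["ptv95"]], constraints))
    reasons <- c(reasons, sprintf(
      "PTV coverage compromised: optimized PTV95 %.1f%% below required %.1f%%",
      metrics_optimized[["ptv95"]],
      min(constraints$ptv95_floor,
          metrics_initial[["ptv95"]] - constraints$ptv95_drop_tolerance)))
  if (d_ini >= dmean_threshold) {
    if (d_opt >= dmean_threshold)
      reasons <- c(reasons, sprintf(
        "Pmap constraint not met: optimized DmeanPmap %.1f Gy >= %.1f Gy",
        d_opt, dmean_threshold))
    cc <- constraints$constraints
    for (i in seq_len(nrow(cc))) {
      val <- metrics_optimized[[cc$metric[i]]]
      if (is.na(val)) next
      ok <- if (cc$direction[i] == "le") val <= cc$bound[i] else val >= cc$bound[i]
      if (!ok)
        reasons <- c(reasons, sprintf(
          "dose constraint violated: %s = %.1f (bound %s %.1f)",
          cc$metric[i], val, ifelse(cc$direction[i] == "le", "<=", ">="),
          cc$bound[i]))
    }
  } else {
    reduction <- (d_ini - d_opt) / d_ini
    if (reduction < min_relative_reduction)
      reasons <- c(reasons, sprintf(
        "Pmap mean dose reduction %.1f%% below the required %.0f%%",
        100 * reduction, 100 * min_relative_reduction))
  }
  list(success = length(reasons) == 0L, reasons = reasons)
}

mean_ci95 <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (n < 2 || s == 0) return(c(mean = m, lo = m, hi = m))
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

normal_enough <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3L) return(FALSE)
  tryCatch(stats::shapiro.test(x)$p.value >= alpha, error = function(e) FALSE)
}

#' Compare the metric panels of two plan sets
#'
#' Per metric: arm means with t-based 95% CIs and a two-sample p-value. The
#' test is a two-sample t-test when both arms pass a Shapiro-Wilk normality
#' check at alpha = 0.05, and a Mann-Whitney U test otherwise; the test used
#' is recorded per row. The comparison is unpaired, matching the convention
#' of published initial-vs-optimized plan tables; see
#' [reclassification_summary()] for properly paired alternatives.
#'
#' @param initial,optimized Lists of `plan_metrics` (or data frames with
#'   metric columns), at least 3 records per arm.
#' @param metrics Metric fields to compare; defaults to every panel field
#'   present in both arms.
#' @return Data frame with one row per metric: means, CI bounds, `p_value`
#'   and `test_used` (`"t"` or `"mann_whitney"`).
#' @export
compare_plan_sets <- function(initial, optimized, metrics = NULL) {
  to_df <- function(x) {
    if (is.data.frame(x)) return(x)
    as.data.frame(do.call(rbind, lapply(x, unclass)))
  }
  a <- to_df(initial)
  b <- to_df(optimized)
  if (nrow(a) < 3L || nrow(b) < 3L)
    stop("need at least 3 records per arm")
  if (is.null(metrics))
    metrics <- intersect(plan_metric_names(), intersect(names(a), names(b)))
  rows <- lapply(metrics, function(f) {
    xa <- a[[f]][!is.na(a[[f]])]
    xb <- b[[f]][!is.na(b[[f]])]
    if (length(xa) < 3L || length(xb) < 3L) return(NULL)
    ca <- mean_ci95(xa)
    cb <- mean_ci95(xb)
    use_t <- normal_enough(xa) && normal_enough(xb)
    if (use_t) {
      p <- stats::t.test(xa, xb)$p.value
    } else {
      p <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
    }
    data.frame(metric = f,
               mean_initial = ca[["mean"]], ci_lo_initial = ca[["lo"]],
               ci_hi_initial = ca[["hi"]],
               mean_optimized = cb[["mean"]], ci_lo_optimized = cb[["lo"]],
               ci_hi_optimized = cb[["hi"]],
               p_value = p,
               test_used = if (use_t) "t" else "mann_whitney",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

boot_median_ci <- function(x, n_boot = 2000, seed = 1) {
  if (length(x) < 2L) return(c(lo = stats::median(x), hi = stats::median(x)))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  meds <- replicate(n_boot, stats::median(sample(x, replace = TRUE)))
  q <- stats::quantile(meds, c(0.025, 0.975), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Reclassification summary for paired APT probabilities
#'
#' For each patient the initial and optimized predicted APT probabilities
#' are dichotomised at the decision threshold (8% by default) and the
#' transitions are counted. Paired significance is assessed two ways: an
#' exact McNemar test (binomial test on the discordant transition counts)
#' on the class changes, and a Wilcoxon signed-rank test on the probability
#' pairs.
#'
#' @param prob_initial,prob_optimized Probability vectors of equal length.
#' @param threshold Decision threshold (default 0.08).
#' @param n_boot Bootstrap resamples for the median CIs.
#' @param seed Seed for the bootstrap.
#' @return List with transition counts (`high_to_low`, `low_to_high`,
#'   `stays_high`, `stays_low`), `n`, `reclassified_fraction` (all class
#'   changes / n), `high_to_low_fraction`, per-plan mean/median summaries
#'   with 95% CIs, `p_mcnemar_exact` and `p_wilcoxon_paired`.
#' @export
reclassification_summary <- function(prob_initial, prob_optimized,
                                     threshold = 0.08, n_boot = 2000,
                                     seed = 1) {
  if (length(prob_initial) == 0L) stop("empty input")
  if (length(prob_initial) != length(prob_optimized))
    stop("probability vectors must have equal length")
  ci <- classify_by_prob(prob_initial, threshold)
  co <- classify_by_prob(prob_optimized, threshold)
  n <- length(ci)
  h2l <- sum(ci == "high" & co == "low")
  l2h <- sum(ci == "low" & co == "high")
  disc <- h2l + l2h
  p_mcnemar <- if (disc == 0L) 1 else
    stats::binom.test(h2l, disc, p = 0.5)$p.value
  p_wilcox <- if (all(prob_initial == prob_optimized)) 1 else
    suppressWarnings(stats::wilcox.test(prob_initial, prob_optimized,
                                        paired = TRUE, exact = FALSE)$p.value)
  summarise_arm <- function(p, s) {
    med_ci <- boot_median_ci(p, n_boot = n_boot, seed = s)
    mc <- mean_ci95(p)
    list(mean = mc[["mean"]], mean_ci = c(mc[["lo"]], mc[["hi"]]),
         median = stats::median(p), median_ci = unname(med_ci))
  }
  list(n = n,
       high_to_low = h2l, low_to_high = l2h,
       stays_high = sum(ci == "high" & co == "high"),
       stays_low = sum(ci == "low" & co == "low"),
       reclassified_fraction = disc / n,
       high_to_low_fraction = h2l / n,
       initial = summarise_arm(prob_initial, seed),
       optimized = summarise_arm(prob_optimized, seed + 1),
       p_mcnemar_exact = p_mcnemar,
       p_wilcoxon_paired = p_wilcox,
       threshold = threshold)
}

#' ROC of the PTV-Pmap Dice score against optimization failure
#'
#' Evaluates the PTV-Pmap Dice overlap as a predictor of \emph{unsuccessful}
#' optimization (higher overlap makes sparing the sub-region harder), the
#' orientation under which published discrimination is reported. The AUC is
#' the Mann-Whitney probability that a failed patient carries a higher Dice
#' than a successful one; the operating cutoff maximises the Youden index
#' (sensitivity + specificity - 1).
#'
#' @param dice_values Numeric scores in `[0, 1]`.
#' @param success_flags Logical; `TRUE` for successful optimization.
#' @return List of class `roc_result`: `auc`, `youden_cutoff`,
#'   `sensitivity`, `specificity` at the cutoff, class counts, and
#'   `orientation` (positive class = failure; higher Dice predicts failure).
#' @export
roc_dice_vs_success <- function(dice_values, success_flags) {
  if (length(dice_values) != length(success_flags))
    stop("inputs must have equal length")
  if (any(!is.finite(dice_values)) || dice_values_out_of_range(dice_values))
    stop("Dice scores must be finite values in [0, 1]")
  if (any(is.na(success_flags))) stop("missing success flag")
  failure <- !as.logical(success_flags)
  if (length(unique(failure)) < 2L)
    stop("both successful and unsuccessful patients are required for ROC")
  r <- pROC::roc(response = factor(failure, levels = c(FALSE, TRUE)),
                 predictor = dice_values, direction = "<",
                 levels = c(FALSE, TRUE), quiet = TRUE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]
  structure(list(auc = as.numeric(pROC::auc(r)),
                 youden_cutoff = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 n_failure = sum(failure), n_success = sum(!failure),
                 orientation = "positive class = optimization failure; higher Dice predicts failure"),
            class = "roc_result")
}

dice_values_out_of_range <- function(x) any(x < 0 | x > 1)

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (failures %d vs successes %d)\n  Youden cutoff %.3f: sensitivity %.2f, specificity %.2f\n  %s\n",
    x$auc, x$n_failure, x$n_success, x$youden_cutoff, x$sensitivity,
    x$specificity, x$orientation))
  invisible(x)
}
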