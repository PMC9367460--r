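#' Canonical feature order of the APT risk model
#'
#' The 11 features, in declared importance order, that drive the acute
#' pulmonary toxicity (APT) probability model: the mean BED dose to the Pmap
#' sub-region, combined-lung and homolateral-lung DVH metrics, heart V40,
#' and the clinical covariates smoking status, MEVS (mean expiratory volume
#' per second, % of theoretical value), COPD and AJCC stage.
#'
#' @return Character vector of the 11 feature names.
#' @export
risk_feature_names <- function() {
  c("dmean_pmap_bed", "dmean_2lungs", "v30_2lungs", "smoking_status",
    "mevs", "copd", "v10_lungh", "ajcc_stage", "v5_lungh", "dmean_lungh",
    "v40_heart")
}

#' Ordinal encoding of AJCC stage
#'
#' @param stage Character vector of stages (`"IIIA"`, `"IIIB"`, `"IIIC"`) or
#'   already-numeric codes.
#' @param levels Declared category set, encoded 0, 1, 2, ... in order.
#' @return Numeric codes.
#' @export
encode_ajcc_stage <- function(stage, levels = c("IIIA", "IIIB", "IIIC")) {
  if (is.numeric(stage)) return(as.numeric(stage))
  idx <- match(stage, levels)
  if (any(is.na(idx)))
    stop("unknown AJCC stage value(s): ",
         paste(unique(stage[is.na(idx)]), collapse = ", "))
  idx - 1
}

#' APT risk model
#'
#' A pluggable probability model for grade >= 2 APT over the 11-feature
#' vector of [risk_feature_names()], with the two published decision
#' thresholds attached: a predicted probability of 8% and a mean Pmap BED
#' dose of 30.3 Gy. Backends:
#' \describe{
#'   \item{threshold_only}{No probability model; only the Dmean threshold
#'     rule is available.}
#'   \item{logistic_surrogate}{`p = plogis(intercept + w . f)` with named
#'     weights over the 11 features. Used for synthetic studies and testing;
#'     it makes no claim to reproduce the originally trained model, whose
#'     coefficients are unpublished.}
#'   \item{external}{Weights/intercept loaded from a serialized JSON file in
#'     the same logistic form.}
#' }
#'
#' @param kind Backend, see above.
#' @param weights Named numeric vector over [risk_feature_names()]
#'   (logistic backends).
#' @param intercept Numeric intercept (logistic backends).
#' @param prob_threshold Probability decision threshold, default 0.08.
#' @param dmean_threshold Pmap mean-BED-dose threshold in Gy, default 30.3.
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(kind = c("logistic_surrogate", "threshold_only",
                                "external"),
                       weights = NULL, intercept = NULL,
                       prob_threshold = 0.08, dmean_threshold = 30.3) {
  kind <- match.arg(kind)
  if (!is.numeric(prob_threshold) || prob_threshold <= 0 || prob_threshold >= 1)
    stop("'prob_threshold' must be in (0, 1)")
  if (!is.numeric(dmean_threshold) || dmean_threshold <= 0)
    stop("'dmean_threshold' must be > 0 Gy")
  if (kind != "threshold_only") {
    fn <- risk_feature_names()
    if (is.null(weights) || is.null(names(weights)) ||
        !setequal(names(weights), fn))
      stop("logistic model needs 'weights' named over all 11 risk features")
    if (!is.numeric(intercept) || length(intercept) != 1L)
      stop("logistic model needs a scalar 'intercept'")
    weights <- weights[fn]
  }
  structure(list(kind = kind, weights = weights, intercept = intercept,
                 prob_threshold = prob_threshold,
                 dmean_threshold = dmean_threshold),
            class = "risk_model")
}

#' Classify APT risk from the Pmap mean BED dose
#'
#' High risk iff the mean Pmap dose (BED, alpha/beta = 3 Gy) is at least
#' the threshold (inclusive), 30.3 Gy by default.
#'
#' @param dmean_pmap_bed Mean Pmap BED dose in Gy (vectorised).
#' @param threshold Decision threshold in Gy.
#' @return Character vector, `"high"` or `"low"`.
#' @examples
#' classify_by_dmean(c(36.5, 24.8, 30.3))
#' @export
classify_by_dmean <- function(dmean_pmap_bed, threshold = 30.3) {
  if (any(!is.finite(dmean_pmap_bed))) stop("dose must be finite")
  ifelse(dmean_pmap_bed >= threshold, "high", "low")
}

#' Classify APT risk from a predicted probability
#'
#' High risk iff the predicted probability is at least the threshold
#' (inclusive), 8% by default.
#'
#' @param p Probability in `[0, 1]` (vectorised).
#' @param threshold Decision threshold as a fraction.
#' @return Character vector, `"high"` or `"low"`.
#' @export
classify_by_prob <- function(p, threshold = 0.08) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("'p' must be probabilities in [0, 1]")
  ifelse(p >= threshold, "high", "low")
}

encode_features <- function(features) {
  fn <- risk_feature_names()
  if (is.data.frame(features)) {
    missing <- setdiff(fn, names(features))
    if (length(missing) > 0)
      stop("missing risk feature(s): ", paste(missing, collapse = ", "))
    f <- features[fn]
    if (is.character(f$ajcc_stage) || is.factor(f$ajcc_stage))
      f$ajcc_stage <- encode_ajcc_stage(as.character(f$ajcc_stage))
    m <- as.matrix(as.data.frame(lapply(f, as.numeric)))
  } else {
    missing <- setdiff(fn, names(features))
    if (length(missing) > 0)
      stop("missing risk feature(s): ", paste(missing, collapse = ", "))
    m <- matrix(as.numeric(features[fn]), nrow = 1,
                dimnames = list(NULL, fn))
  }
  if (any(!is.finite(m)))
    stop("non-finite value in encoded risk features")
  m
}

#' Predict the probability of grade >= 2 APT
#'
#' @param features Named numeric vector, or data frame with one row per
#'   patient, holding all 11 features of [risk_feature_names()];
#'   `ajcc_stage` may be given as stage labels and is encoded ordinally.
#' @param model A logistic-backend [risk_model()].
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict_prob_apt <- function(features, model) {
  stopifnot(inherits(model, "risk_model"))
  if (model$kind == "threshold_only")
    stop("a threshold_only model has no probability backend; ",
         "use classify_by_dmean()")
  m <- encode_features(features)
  as.numeric(stats::plogis(model$intercept +
                             m %*% model$weights[colnames(m)]))
}

#' Fit a logistic surrogate APT model
#'
#' Maximum-likelihood logistic regression of a binary APT outcome on the 11
#' risk features. A per-feature importance analogue is reported as the share
#' of the standardized absolute weight, `|w_j| * sd(x_j)` normalised to sum
#' to 1.
#'
#' @param cohort Data frame with the 11 feature columns plus an `apt` binary
#'   outcome column; at least 50 records and both outcome classes required.
#' @param prob_threshold,dmean_threshold Thresholds stored on the returned
#'   model.
#' @return A `logistic_surrogate` [risk_model()] with an `importance`
#'   attribute (named shares summing to 1) and a `fit` attribute holding the
#'   `glm` object.
#' @export
fit_surrogate <- function(cohort, prob_threshold = 0.08,
                          dmean_threshold = 30.3) {
  if (!is.data.frame(cohort) || !"apt" %in% names(cohort))
    stop("'cohort' must be a data frame with an 'apt' outcome column")
  if (nrow(cohort) < 50L)
    stop("need at least 50 records to fit the surrogate model")
  y <- cohort$apt
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("outcome 'apt' must be binary with both classes present")
  x <- as.data.frame(encode_features(cohort))
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("degenerate design: constant feature(s) ",
         paste(names(sds)[sds == 0], collapse = ", "))
  dat <- cbind(x, apt = y)
  fit <- suppressWarnings(stats::glm(apt ~ ., data = dat,
                                     family = stats::binomial()))
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 50))
    stop("logistic fit did not converge cleanly; ",
         "possible (quasi-)separation in the design")
  w <- stats::coef(fit)[risk_feature_names()]
  std_w <- abs(w) * sds[risk_feature_names()]
  m <- risk_model("logistic_surrogate", weights = w,
                  intercept = stats::coef(fit)[["(Intercept)"]],
                  prob_threshold = prob_threshold,
                  dmean_threshold = dmean_threshold)
  attr(m, "importance") <- std_w / sum(std_w)
  attr(m, "fit") <- fit
  m
}

#' Write / read a risk model as JSON
#'
#' Serializes feature order, weights, intercept and thresholds so externally
#' trained logistic models can be plugged in.
#'
#' @param model A logistic-backend [risk_model()].
#' @param path File path.
#' @return `write_risk_model` returns `path` invisibly; `read_risk_model`
#'   returns a [risk_model()] of kind `"external"`.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  if (model$kind == "threshold_only")
    stop("threshold_only models carry no parameters to serialize")
  jsonlite::write_json(list(
    feature_order = risk_feature_names(),
    weights = as.list(model$weights),
    intercept = model$intercept,
    prob_threshold = model$prob_threshold,
    dmean_threshold = model$dmean_threshold
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("feature_order", "weights", "intercept"))
    if (is.null(j[[f]])) stop("model file missing field '", f, "'")
  risk_model("external", weights = unlist(j$weights), intercept = j$intercept,
             prob_threshold = j$prob_threshold %||% 0.08,
             dmean_threshold = j$dmean_threshold %||% 30.3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
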