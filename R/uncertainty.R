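# Decision and uncertainty taxonomies.
#
# A risk prediction is binarized at a threshold (5% by default, 10% as the
# alternative). An AI prediction is "uncertain" when the threshold lies
# inside its 95% predictive interval (CI-enclosure rule). A case carries
# high physician uncertainty when at least one of its two reviewers scored
# confidence below 4 on the 5-point Likert scale.

#' Uncertainty configuration
#'
#' @param risk_threshold Decision threshold on the probability scale
#'   (default 0.05; the alternative analysis uses 0.10).
#' @param physician_confidence_cut Likert cut; confidence below this value
#'   marks an uncertain reviewer (default 4).
#' @return A list of class `uncertainty_config`.
#' @export
uncertainty_config <- function(risk_threshold = 0.05,
                               physician_confidence_cut = 4L) {
  stopifnot(risk_threshold > 0, risk_threshold < 1,
            physician_confidence_cut %in% 1:5)
  structure(list(risk_threshold = risk_threshold,
                 physician_confidence_cut = as.integer(physician_confidence_cut)),
            class = "uncertainty_config")
}

#' Binarize predicted risk at a threshold
#'
#' Positive iff `mean >= threshold`: a prediction exactly at the threshold is
#' positive, matching the reading that only risks strictly below the
#' threshold are low-risk.
#'
#' @param mean Predicted probabilities.
#' @param threshold Decision threshold.
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
binarize_risk <- function(mean, threshold = 0.05) {
  stop_if_not_prob(mean, "mean")
  ifelse(mean >= threshold, "positive", "negative")
}

#' Classify AI prediction uncertainty by CI enclosure
#'
#' High uncertainty iff the decision threshold lies inside the closed 95%
#' predictive interval, `ci_low <= threshold <= ci_high`; this couples the
#' point estimate and its dispersion in one rule.
#'
#' @param pred Posterior-prediction data.frame with `ci_low` and `ci_high`
#'   (see [predict_bnn()]).
#' @param threshold Decision threshold.
#' @return Character vector of `"high"` / `"low"`.
#' @export
classify_ai_uncertainty <- function(pred, threshold = 0.05) {
  stopifnot(all(c("ci_low", "ci_high") %in% names(pred)))
  ifelse(pred$ci_low <= threshold & threshold <= pred$ci_high,
         "high", "low")
}

#' Classify physician uncertainty from paired reviewer confidences
#'
#' High uncertainty iff at least one of the two reviewing physicians scored
#' confidence below `cut` points; low iff both scored `cut` or higher.
#'
#' @param conf_a,conf_b Likert confidences (1-5) of the two reviewers.
#' @param cut Likert cut (default 4).
#' @return Character vector of `"high"` / `"low"`.
#' @export
classify_physician_uncertainty <- function(conf_a, conf_b, cut = 4L) {
  if (any(!(c(conf_a, conf_b) %in% 1:5))) {
    stop("confidence scores must lie in 1..5")
  }
  ifelse(pmin(conf_a, conf_b) < cut, "high", "low")
}
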