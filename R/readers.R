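# Simulated two-reader pre/post-AI rating behaviour.
#
# Each case set is reviewed by exactly two readers. A reader's pre-AI rating
# is a noisy gestalt: the generative log-odds plus reader bias and
# per-review noise, binned on the ordinal probability scale
# (very low 0-5%, low 5-10%, low-moderate 10-20%, moderate 20-50%,
# high 50-100%). The post-AI rating is anchor-and-adjust on the probability
# scale: a convex combination of the reader's gestalt probability and the AI
# point estimate, with a weight that increases when the AI is certain
# (CI-enclosure rule) and decreases with the reader's own confidence.

BIN_EDGES <- c(0.05, 0.10, 0.20, 0.50)

#' Bin a probability onto the 5-level ordinal risk scale
#'
#' Half-open intervals `[0,0.05) [0.05,0.10) [0.10,0.20) [0.20,0.50)
#' [0.50,1]`, returning bins 1 (very low) to 5 (high).
#'
#' @param p Probabilities.
#' @param edges Strictly increasing cutpoints inside (0, 1).
#' @return Integer bins 1..(length(edges) + 1).
#' @export
bin_probability <- function(p, edges = BIN_EDGES) {
  stopifnot(all(diff(edges) > 0), all(edges > 0), all(edges < 1))
  stop_if_not_prob(p, "p")
  findInterval(p, edges) + 1L
}

# Default adoption weight: readers lean on the AI more when they are unsure
# and the AI is certain.
default_ai_weight_fn <- function(confidence, ai_uncertainty) {
  base <- (6 - confidence) / 5            # 1 -> 1.0 ... 5 -> 0.2
  mult <- ifelse(ai_uncertainty == "low", 0.75, 0.25)
  pmin(1, pmax(0, base * mult))
}

# Default confidence rule: |gestalt evidence| (log-odds distance from the
# low/low-moderate boundary) mapped to Likert 1-5.
default_confidence_rule <- function(evidence_magnitude) {
  cuts <- c(0.9, 1.8, 2.6, 3.4)
  pmin(5L, findInterval(evidence_magnitude, cuts) + 1L)
}

#' Parameters of the simulated reader population
#'
#' @param n_readers Number of readers (two per case set).
#' @param gestalt_noise_sd SD of the per-review gestalt noise (log-odds).
#' @param case_noise_sd SD of the per-case shared gestalt component
#'   (log-odds); both reviewers of a case see the same draw, which creates
#'   inter-reader agreement beyond what the generative risk induces.
#' @param reader_bias_sd SD of the per-reader systematic bias (log-odds).
#' @param confidence_rule Function mapping gestalt-evidence magnitude
#'   (log-odds) to Likert confidence 1-5.
#' @param ai_weight_fn Function `(confidence, ai_uncertainty_class)` ->
#'   adoption weight in `[0, 1]`.
#' @param bin_edges Ordinal cutpoints, default `c(0.05, 0.10, 0.20, 0.50)`.
#' @param risk_threshold Threshold used for the AI CI-enclosure uncertainty
#'   class the readers observe.
#' @param seed Integer seed.
#' @return A list of class `reader_params`.
#' @export
reader_params <- function(n_readers = 20L, gestalt_noise_sd = 2.0,
                          case_noise_sd = 1.0, reader_bias_sd = 0.4,
                          confidence_rule = default_confidence_rule,
                          ai_weight_fn = default_ai_weight_fn,
                          bin_edges = BIN_EDGES, risk_threshold = 0.05,
                          seed = 1L) {
  stopifnot(n_readers >= 2, n_readers %% 2 == 0, gestalt_noise_sd >= 0,
            case_noise_sd >= 0, reader_bias_sd >= 0,
            all(diff(bin_edges) > 0))
  structure(list(n_readers = as.integer(n_readers),
                 gestalt_noise_sd = gestalt_noise_sd,
                 case_noise_sd = case_noise_sd,
                 reader_bias_sd = reader_bias_sd,
                 confidence_rule = confidence_rule,
                 ai_weight_fn = ai_weight_fn, bin_edges = bin_edges,
                 risk_threshold = risk_threshold, seed = as.integer(seed)),
            class = "reader_params")
}

#' Simulate two-reader pre/post-AI ratings for a cohort
#'
#' Cases are partitioned into `n_readers / 2` sets in input order; each set
#' is reviewed separately by two readers. Pre-AI bins come from the noisy
#' gestalt; post-AI bins from the anchor-and-adjust update toward the AI
#' point estimate. Confidence is recomputed post-AI from the updated
#' evidence. Deterministic given `params$seed`.
#'
#' @param cohort Cohort data.frame with `case_id` and `true_risk`.
#' @param ai_predictions Posterior predictions with one row per cohort case
#'   (`case_id`, `mean`, `ci_low`, `ci_high`).
#' @param params A [reader_params()].
#' @return A data.frame of ratings: `case_id`, `reader_id`, `set_id`,
#'   `phase` (`"pre"`/`"post"`), `bin` (1-5), `confidence` (1-5).
#' @export
simulate_readers <- function(cohort, ai_predictions, params = reader_params()) {
  stopifnot(inherits(params, "reader_params"))
  n <- nrow(cohort)
  if (is.null(ai_predictions) ||
      !all(cohort$case_id %in% ai_predictions$case_id)) {
    stop("every case needs an AI prediction")
  }
  ai <- ai_predictions[match(cohort$case_id, ai_predictions$case_id), ]
  n_sets <- params$n_readers %/% 2L
  if (n %% n_sets != 0) {
    stop("number of cases must be divisible by the number of sets")
  }
  set_id <- rep(seq_len(n_sets), each = n %/% n_sets)
  ai_unc <- classify_ai_uncertainty(ai, params$risk_threshold)
  anchor <- logit(pmin(pmax(cohort$true_risk, 1e-6), 1 - 1e-6))
  with_seed(params$seed, {
    bias <- stats::rnorm(params$n_readers, 0, params$reader_bias_sd)
    case_noise <- stats::rnorm(n, 0, params$case_noise_sd)
    out <- vector("list", params$n_readers)
    for (r in seq_len(params$n_readers)) {
      s <- (r + 1L) %/% 2L              # readers 1,2 -> set 1; 3,4 -> set 2
      idx <- which(set_id == s)
      g <- anchor[idx] + case_noise[idx] + bias[r] +
        stats::rnorm(length(idx), 0, params$gestalt_noise_sd)
      p_pre <- stats::plogis(g)
      evidence <- abs(g - logit(0.10))
      conf_pre <- params$confidence_rule(evidence)
      w <- params$ai_weight_fn(conf_pre, ai_unc[idx])
      p_post <- (1 - w) * p_pre + w * ai$mean[idx]
      g_post <- logit(pmin(pmax(p_post, 1e-6), 1 - 1e-6))
      # confidence can only be reinforced by extra information; the AI adds
      # evidence when it is certain
      conf_post <- pmax(conf_pre,
                        params$confidence_rule(abs(g_post - logit(0.10)) +
                                                 ifelse(ai_unc[idx] == "low",
                                                        0.4, 0)))
      out[[r]] <- data.frame(
        case_id = rep(cohort$case_id[idx], 2),
        reader_id = sprintf("reader_%02d", r),
        set_id = s,
        phase = rep(c("pre", "post"), each = length(idx)),
        bin = c(bin_probability(p_pre, params$bin_edges),
                bin_probability(p_post, params$bin_edges)),
        confidence = c(conf_pre, conf_post),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Write / read reader ratings as CSV
#'
#' Columns: `case_id`, `reader_id`, `set_id`, `phase` (pre/post), `bin`
#' (1-5), `confidence` (1-5).
#'
#' @param ratings Ratings data.frame.
#' @param path File path.
#' @return `write_ratings` returns the path invisibly; `read_ratings` the
#'   data.frame.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
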