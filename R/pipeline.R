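# Two-phase orchestration: model development/validation (Phase 1) and the
# simulated reader study (Phase 2). The analysis/ scripts are thin drivers
# over these two functions.

#' Run Phase 1: train, validate, and characterize the model
#'
#' Trains the full two-branch model plus the structured-only and text-only
#' ablations on the development cohort, then evaluates on the validation
#' cohort: DeLong AUC for each model, sensitivity/specificity/PPV/NPV with
#' Wilson CIs at each risk threshold (5% and 10% by default), a decile
#' calibration table, the fraction of high-uncertainty predictions
#' (CI-enclosure rule), and permutation-Shapley global feature importance.
#'
#' @param dev_cohort Development cohort (with `label`, `note`).
#' @param val_cohort Validation cohort.
#' @param config A [bnn_config()] for the full model; ablations reuse it
#'   with `model_kind` switched.
#' @param thresholds Risk thresholds to report (default `c(0.05, 0.10)`).
#' @param shap_n Number of validation cases explained for global importance
#'   (0 skips the Shapley stage).
#' @param out_dir Optional directory; when given, the report is written as
#'   JSON + CSV files.
#' @return A list report: `models` (trained fits), `predictions`,
#'   `auc` (per model), `threshold_metrics`, `calibration`,
#'   `uncertainty_fraction`, `mean_ci_width`, `importance`.
#' @export
run_phase1 <- function(dev_cohort, val_cohort, config = bnn_config(),
                       thresholds = c(0.05, 0.10), shap_n = 25L,
                       out_dir = NULL) {
  stopifnot(nrow(dev_cohort) > 0, nrow(val_cohort) > 0)
  kinds <- c("full", "structured_only", "text_only")
  models <- lapply(kinds, function(k) {
    train_bnn(dev_cohort, utils::modifyList(config, list(model_kind = k)))
  })
  names(models) <- kinds
  preds <- lapply(models, function(m) {
    predict_bnn(m, val_cohort, seed = config$seed + 7L)
  })
  auc <- lapply(preds, function(p) roc_auc_delong(p$mean, val_cohort$label))
  thr_metrics <- list()
  for (th in thresholds) {
    bin <- binarize_risk(preds$full$mean, th)
    thr_metrics[[sprintf("threshold_%g", th)]] <-
      confusion_metrics(bin, val_cohort$label)
  }
  calib <- calibration_table(preds$full$mean, val_cohort$label)
  unc <- classify_ai_uncertainty(preds$full, thresholds[1])
  importance <- NULL
  if (shap_n > 0) {
    idx <- with_seed(config$seed + 11L,
                     sample.int(nrow(val_cohort), min(shap_n, nrow(val_cohort))))
    importance <- shapley_global_importance(
      models$full, val_cohort[idx, , drop = FALSE],
      background = val_cohort[idx, , drop = FALSE],
      n_permutations = 10L, seed = config$seed + 13L)
  }
  report <- list(
    models = models, predictions = preds, auc = auc,
    threshold_metrics = thr_metrics, calibration = calib,
    uncertainty_fraction = mean(unc == "high"),
    mean_ci_width = mean(preds$full$ci_high - preds$full$ci_low),
    importance = importance,
    n_dev = nrow(dev_cohort), n_val = nrow(val_cohort)
  )
  if (!is.null(out_dir)) write_phase1_report(report, out_dir)
  report
}

#' @rdname run_phase1
#' @param report A `run_phase1()` report.
#' @export
write_phase1_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- list(
    n_dev = report$n_dev, n_val = report$n_val,
    auc = lapply(report$auc, function(a) {
      list(auc = a$auc, ci_low = a$ci_low, ci_high = a$ci_high)
    }),
    uncertainty_fraction = report$uncertainty_fraction,
    mean_ci_width = report$mean_ci_width
  )
  jsonlite::write_json(scalars, file.path(out_dir, "phase1_summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  for (nm in names(report$threshold_metrics)) {
    utils::write.csv(report$threshold_metrics[[nm]],
                     file.path(out_dir, paste0("phase1_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$calibration,
                   file.path(out_dir, "phase1_calibration.csv"),
                   row.names = FALSE)
  if (!is.null(report$importance)) {
    utils::write.csv(report$importance,
                     file.path(out_dir, "phase1_importance.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

# Pooled two-rater kappa of a phase: pairs the two readers of each set.
phase_kappa <- function(ratings, phase) {
  sub <- ratings[ratings$phase == phase, , drop = FALSE]
  sp <- split(sub, sub$case_id)
  pairs <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$reader_id), , drop = FALSE]
    data.frame(a = d$bin[1], b = d$bin[2])
  }))
  weighted_kappa(pairs$a, pairs$b)
}

#' Run Phase 2: simulated reader study and MRMC analysis
#'
#' Samples a case subset, allocates it to `n_readers / 2` sets of equal size
#' each reviewed by two simulated readers, simulates pre/post-AI ratings,
#' and computes: the pooled pre- vs post-AI OR MRMC comparison,
#' reader-averaged ROC curves, sensitivity/specificity at the 5% threshold
#' (a rating is positive when the ordinal bin is above "very low"), weighted
#' kappa between paired readers pre and post, the paired confidence t-test,
#' the very-low vs low-high transition matrix, and MRMC comparisons within
#' the four uncertainty subgroups.
#'
#' @param cohort Cohort to sample cases from (with `true_risk`, `label`).
#' @param predictions AI posterior predictions for the cohort (e.g.,
#'   [predict_bnn()] output with `case_id`).
#' @param params A [reader_params()].
#' @param n_cases Total sampled cases (must be divisible by the number of
#'   sets).
#' @param threshold Risk threshold for binarized comparisons (5% only, per
#'   the sensitivity rationale).
#' @param out_dir Optional output directory for JSON/CSV reports.
#' @param seed Seed for the case sampling.
#' @return A list report with `mrmc`, `mrmc_subgroups`, `subgroup_sizes`,
#'   `kappa_pre`, `kappa_post`, `confidence_test`, `transitions`,
#'   `reader_metrics`, `ai_metrics`, `average_roc`, `ratings`, `cases`.
#' @export
run_phase2 <- function(cohort, predictions, params = reader_params(),
                       n_cases = 1000L, threshold = 0.05, out_dir = NULL,
                       seed = 1L) {
  n_sets <- params$n_readers %/% 2L
  if (n_cases > nrow(cohort)) stop("not enough cases to sample from")
  if (n_cases %% n_sets != 0) {
    stop("n_cases must be divisible by the number of case sets")
  }
  idx <- with_seed(seed, sample.int(nrow(cohort), n_cases))
  cases <- cohort[idx, , drop = FALSE]
  preds <- predictions[match(cases$case_id, predictions$case_id), ,
                       drop = FALSE]
  if (anyNA(preds$mean)) stop("every sampled case needs an AI prediction")
  ratings <- simulate_readers(cases, preds, params)
  labels <- stats::setNames(cases$label, cases$case_id)
  mrmc <- or_mrmc_compare(ratings, labels)
  # reader-averaged ROC curves per phase
  avg_roc <- lapply(c(pre = "pre", post = "post"), function(ph) {
    curves <- lapply(split(ratings[ratings$phase == ph, ],
                           ratings$reader_id[ratings$phase == ph]),
                     function(d) roc_curve(d$bin, labels[d$case_id]))
    average_roc(curves)
  })
  # binarized reader metrics at the 5% threshold: positive iff bin >= 2
  reader_metrics <- lapply(c(pre = "pre", post = "post"), function(ph) {
    d <- ratings[ratings$phase == ph, , drop = FALSE]
    confusion_metrics(d$bin >= 2L, labels[d$case_id])
  })
  ai_metrics <- confusion_metrics(binarize_risk(preds$mean, threshold),
                                  cases$label)
  ai_unc <- stats::setNames(classify_ai_uncertainty(preds, threshold),
                            cases$case_id)
  phys_unc <- case_physician_uncertainty(ratings)
  subgroups <- subgroup_stratify(ratings, ai_unc, phys_unc)
  mrmc_sub <- mrmc_by_subgroup(ratings, labels, subgroups)
  pre_bins <- ratings[ratings$phase == "pre", ]
  post_bins <- ratings[ratings$phase == "post", ]
  ord <- order(pre_bins$case_id, pre_bins$reader_id)
  ord2 <- order(post_bins$case_id, post_bins$reader_id)
  grouping <- c(`1` = "very low", `2` = "low-high", `3` = "low-high",
                `4` = "low-high", `5` = "low-high")
  report <- list(
    mrmc = mrmc, mrmc_subgroups = mrmc_sub,
    subgroup_sizes = vapply(subgroups, length, integer(1)),
    kappa_pre = phase_kappa(ratings, "pre"),
    kappa_post = phase_kappa(ratings, "post"),
    confidence_test = paired_confidence_test(
      pre_bins$confidence[ord], post_bins$confidence[ord2]),
    transitions = transition_matrix(pre_bins$bin[ord], post_bins$bin[ord2],
                                    grouping),
    reader_metrics = reader_metrics, ai_metrics = ai_metrics,
    average_roc = avg_roc,
    ai_auc = roc_auc_delong(preds$mean, cases$label),
    ratings = ratings, cases = cases
  )
  if (!is.null(out_dir)) write_phase2_report(report, out_dir)
  report
}

#' @rdname run_phase2
#' @param report A `run_phase2()` report.
#' @export
write_phase2_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mr <- function(m) {
    if (is.null(m)) return(NULL)
    list(auc_pre = m$auc_pre, auc_post = m$auc_post,
         difference = m$difference, F = m$F, ddf = m$ddf,
         p_value = m$p_value, ci_low = m$ci_low, ci_high = m$ci_high,
         n_cases = attr(m, "n_cases"))
  }
  scalars <- list(
    total = mr(report$mrmc),
    subgroups = lapply(report$mrmc_subgroups, mr),
    subgroup_sizes = as.list(report$subgroup_sizes),
    kappa_pre = report$kappa_pre, kappa_post = report$kappa_post,
    confidence_test = report$confidence_test,
    ai_auc = list(auc = report$ai_auc$auc, ci_low = report$ai_auc$ci_low,
                  ci_high = report$ai_auc$ci_high)
  )
  jsonlite::write_json(scalars, file.path(out_dir, "phase2_summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  utils::write.csv(as.data.frame(report$transitions),
                   file.path(out_dir, "phase2_transitions.csv"),
                   row.names = FALSE)
  write_ratings(report$ratings, file.path(out_dir, "phase2_ratings.csv"))
  invisible(out_dir)
}
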