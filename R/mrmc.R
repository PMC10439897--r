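# Multi-reader multi-case comparison of pre- vs post-AI reader performance.
#
# Obuchowski-Rockette ANOVA on the reader-by-modality AUC matrix with
# case-jackknife error covariances and the Hillis denominator degrees of
# freedom. Handles the split-plot allocation in which readers are nested in
# disjoint case sets (two readers per set): jackknife covariances are
# computed for reader pairs sharing a case set, set to zero across disjoint
# sets, and averaged over all pairs, which keeps the crossed-design F
# denominator unbiased for this design.

#' Empirical AUC of one reader's ordinal ratings
#'
#' Ordinal bins are used directly as scores; the AUC is the Mann-Whitney
#' statistic with half credit for ties (equivalently the trapezoidal area).
#'
#' @param bins Ordinal ratings (1-5) of one reader in one phase.
#' @param labels Binary case labels aligned with `bins`.
#' @return The AUC (scalar).
#' @export
reader_auc <- function(bins, labels) {
  auc_placements(as.numeric(bins), as.integer(labels))$auc
}

# Leave-one-case-out AUCs from placements; O(n log n) overall.
jackknife_aucs <- function(scores, labels) {
  pl <- auc_placements(scores, labels)
  if (pl$n1 < 2 || pl$n0 < 2) {
    stop("case jackknife requires at least two cases of each class")
  }
  out <- numeric(length(scores))
  pos <- which(labels == 1); neg <- which(labels == 0)
  out[pos] <- (pl$n1 * pl$auc - pl$v_pos) / (pl$n1 - 1)
  out[neg] <- (pl$n0 * pl$auc - pl$v_neg) / (pl$n0 - 1)
  out
}

jack_cov <- function(a, b) {
  n <- length(a)
  (n - 1) / n * sum((a - mean(a)) * (b - mean(b)))
}

#' Obuchowski-Rockette comparison of two rating modalities
#'
#' Computes the reader-by-modality AUC matrix, case-jackknife estimates of
#' the error variance and covariances (Cov1: same reader, different
#' modality; Cov2: different reader, same modality; Cov3: different reader,
#' different modality), and the OR F-test for the modality effect with the
#' Hillis denominator degrees of freedom
#' `F = MS(T) / (MS(T*R) + r * max(Cov2 - Cov3, 0))`.
#' Reader pairs rating disjoint case sets contribute zero covariance
#' (split-plot allocation); pairs must rate either identical or disjoint
#' case sets.
#'
#' @param ratings Data.frame with `case_id`, `reader_id`, `phase`
#'   (`"pre"`/`"post"`), and a score column (default `bin`). Every reader
#'   must have both phases on the same cases.
#' @param labels Named binary vector (names are case ids), or a data.frame
#'   with `case_id` and `label`.
#' @param score_col Name of the score column.
#' @param conf_level Confidence level for the difference CI.
#' @return A list of class `mrmc_result`: per-reader AUC matrix, pooled
#'   `auc_pre`/`auc_post`, `difference` (post minus pre), `F`, `df1`, `ddf`
#'   (Hillis), `p_value`, `ci_low`/`ci_high` of the difference, and the
#'   covariance `components`.
#' @export
or_mrmc_compare <- function(ratings, labels, score_col = "bin",
                            conf_level = 0.95) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$case_id)
  }
  readers <- sort(unique(ratings$reader_id))
  r <- length(readers)
  if (r < 2) stop("at least two readers are required")
  phases <- c("pre", "post")
  case_sets <- list()
  jack <- list()
  theta <- matrix(NA_real_, r, 2, dimnames = list(readers, phases))
  for (i in seq_len(r)) {
    for (j in 1:2) {
      sel <- ratings$reader_id == readers[i] & ratings$phase == phases[j]
      if (!any(sel)) {
        stop(sprintf("reader '%s' is missing phase '%s'", readers[i],
                     phases[j]))
      }
      sub <- ratings[sel, , drop = FALSE]
      if (anyDuplicated(sub$case_id)) {
        stop("duplicate rating for a (case, reader, phase) combination")
      }
      sub <- sub[order(sub$case_id), , drop = FALSE]
      cs <- sub$case_id
      if (j == 1) {
        case_sets[[i]] <- cs
      } else if (!identical(case_sets[[i]], cs)) {
        stop("a reader must rate the same cases in both phases")
      }
      y <- labels[cs]
      if (anyNA(y)) stop("missing label for a rated case")
      theta[i, j] <- reader_auc(sub[[score_col]], y)
      jack[[paste(i, j)]] <- jackknife_aucs(as.numeric(sub[[score_col]]),
                                            as.integer(y))
    }
  }
  shares <- function(i, k) {
    if (identical(case_sets[[i]], case_sets[[k]])) return(TRUE)
    if (length(intersect(case_sets[[i]], case_sets[[k]])) > 0) {
      stop("reader case sets must be identical or disjoint")
    }
    FALSE
  }
  # error variance: mean jackknife variance over reader-modality cells
  var_error <- mean(vapply(jack, function(a) jack_cov(a, a), numeric(1)))
  # Cov1: same reader, different modality
  cov1 <- mean(vapply(seq_len(r), function(i) {
    jack_cov(jack[[paste(i, 1)]], jack[[paste(i, 2)]])
  }, numeric(1)))
  # Cov2 / Cov3: averaged over ALL reader pairs, zero when disjoint
  c2 <- c3 <- 0
  n_pairs <- 0
  for (i in seq_len(r - 1)) {
    for (k in (i + 1):r) {
      n_pairs <- n_pairs + 1
      if (!shares(i, k)) next
      c2 <- c2 + (jack_cov(jack[[paste(i, 1)]], jack[[paste(k, 1)]]) +
                    jack_cov(jack[[paste(i, 2)]], jack[[paste(k, 2)]])) / 2
      c3 <- c3 + (jack_cov(jack[[paste(i, 1)]], jack[[paste(k, 2)]]) +
                    jack_cov(jack[[paste(i, 2)]], jack[[paste(k, 1)]])) / 2
    }
  }
  cov2 <- c2 / n_pairs
  cov3 <- c3 / n_pairs
  # OR ANOVA on the AUC matrix (t = 2 modalities)
  t_mod <- 2
  grand <- mean(theta)
  col_means <- colMeans(theta)
  row_means <- rowMeans(theta)
  ms_t <- r * sum((col_means - grand)^2) / (t_mod - 1)
  resid <- theta - outer(row_means, rep(1, t_mod)) -
    outer(rep(1, r), col_means) + grand
  ms_tr <- sum(resid^2) / ((t_mod - 1) * (r - 1))
  denom <- ms_tr + r * max(cov2 - cov3, 0)
  if (denom <= 0 || ms_t == 0) {
    f_stat <- 0
    ddf <- Inf
    p <- 1
  } else {
    f_stat <- ms_t / denom
    ddf <- if (ms_tr == 0) Inf else
      denom^2 / (ms_tr^2 / ((t_mod - 1) * (r - 1)))
    p <- stats::pf(f_stat, t_mod - 1, ddf, lower.tail = FALSE)
  }
  difference <- col_means["post"] - col_means["pre"]
  se_diff <- sqrt(max(0, 2 * denom / r))
  tq <- if (is.finite(ddf)) stats::qt(1 - (1 - conf_level) / 2, ddf)
        else stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    auc_matrix = theta,
    auc_pre = unname(col_means["pre"]), auc_post = unname(col_means["post"]),
    difference = unname(difference),
    F = f_stat, df1 = t_mod - 1, ddf = ddf, p_value = p,
    ci_low = unname(difference - tq * se_diff),
    ci_high = unname(difference + tq * se_diff),
    components = list(var_error = var_error, cov1 = cov1, cov2 = cov2,
                      cov3 = cov3, ms_t = ms_t, ms_tr = ms_tr),
    n_readers = r
  ), class = "mrmc_result")
}

#' @export
print.mrmc_result <- function(x, ...) {
  cat(sprintf("OR MRMC comparison (%d readers)\n", x$n_readers))
  cat(sprintf("  AUC pre  %.4f\n  AUC post %.4f\n", x$auc_pre, x$auc_post))
  cat(sprintf("  diff %.4f (95%% CI %.4f to %.4f), F = %.3f, ddf = %.1f, p = %.4g\n",
              x$difference, x$ci_low, x$ci_high, x$F, x$ddf, x$p_value))
  invisible(x)
}

#' Vertical average of ROC curves
#'
#' Linearly interpolates each curve's sensitivity on the pooled grid of
#' false-positive rates and averages across curves at each grid point.
#'
#' @param curves List of data.frames with `fpr` and `tpr` (see
#'   [roc_curve()]).
#' @return A data.frame with `fpr` and mean `tpr`.
#' @export
average_roc <- function(curves) {
  if (length(curves) == 0) stop("at least one curve is required")
  grid <- sort(unique(unlist(lapply(curves, `[[`, "fpr"))))
  tprs <- vapply(curves, function(cv) {
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(as.matrix(tprs)))
}

#' Weighted Cohen's kappa for paired ordinal ratings
#'
#' `kappa = 1 - sum(w * o) / sum(w * e)` with weights
#' `w_ij = |i - j| / (k - 1)` (linear, default) or squared distances
#' (quadratic); expected counts come from the marginal products.
#'
#' @param a,b Paired ratings on the same cases.
#' @param categories Ordered category set (default 1:5).
#' @param weighting `"linear"` or `"quadratic"`.
#' @return Kappa (scalar).
#' @export
weighted_kappa <- function(a, b, categories = 1:5,
                           weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  if (length(a) != length(b)) stop("ratings must be paired")
  if (length(a) < 2) stop("at least two pairs are required")
  if (!all(c(a, b) %in% categories)) stop("rating outside the category set")
  k <- length(categories)
  fa <- factor(a, levels = categories)
  fb <- factor(b, levels = categories)
  o <- table(fa, fb) / length(a)
  e <- outer(table(fa) / length(a), table(fb) / length(b))
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- if (weighting == "linear") d else d^2
  denom <- sum(w * e)
  if (denom == 0) {
    warning("degenerate marginals: kappa undefined, returning NA")
    return(NA_real_)
  }
  1 - sum(w * o) / denom
}

#' Paired t-test for pre- vs post-AI confidence
#'
#' @param conf_pre,conf_post Paired Likert confidence vectors.
#' @return A list with `t`, `df`, `p_value`, `mean_difference`, and a
#'   `degenerate` flag (TRUE when the difference variance is zero but the
#'   mean difference is nonzero, leaving p undefined).
#' @export
paired_confidence_test <- function(conf_pre, conf_post) {
  if (length(conf_pre) != length(conf_post)) stop("vectors must be paired")
  n <- length(conf_pre)
  if (n < 2) stop("at least two pairs are required")
  d <- as.numeric(conf_post) - as.numeric(conf_pre)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p_value = 1, mean_difference = 0,
                  degenerate = FALSE))
    }
    return(list(t = NA_real_, df = n - 1, p_value = NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(conf_post, conf_pre, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d), degenerate = FALSE)
}

#' Pre-to-post transition counts of ordinal ratings
#'
#' Tallies (pre-group -> post-group) flows after applying an optional
#' grouping of the ordinal bins (e.g., very low vs low-high). Marginals are
#' conserved by construction; unpaired records are an error.
#'
#' @param pre,post Paired ordinal bins of the same case reviews.
#' @param grouping Named character vector mapping bin (as character) to a
#'   display group; `NULL` keeps the raw bins.
#' @return A contingency `table` of counts (pre rows, post columns).
#' @export
transition_matrix <- function(pre, post, grouping = NULL) {
  if (length(pre) != length(post) || anyNA(pre) || anyNA(post)) {
    stop("pre and post ratings must be fully paired")
  }
  if (!is.null(grouping)) {
    pre <- unname(grouping[as.character(pre)])
    post <- unname(grouping[as.character(post)])
    if (anyNA(pre) || anyNA(post)) stop("grouping does not cover all bins")
    levs <- unique(unname(grouping))
  } else {
    levs <- sort(unique(c(pre, post)))
  }
  table(pre = factor(pre, levels = levs), post = factor(post, levels = levs))
}

#' Case-level physician uncertainty from paired reviewer confidences
#'
#' @param ratings Ratings data.frame (both readers of each case present in
#'   the given phase).
#' @param phase Phase whose confidences define the classification
#'   (default `"pre"`).
#' @param cut Likert cut (default 4).
#' @return Named character vector (`"high"`/`"low"`) indexed by case id.
#' @export
case_physician_uncertainty <- function(ratings, phase = "pre", cut = 4L) {
  sub <- ratings[ratings$phase == phase, , drop = FALSE]
  sp <- split(sub$confidence, sub$case_id)
  bad <- vapply(sp, length, integer(1)) != 2
  if (any(bad)) stop("each case must have exactly two reviews per phase")
  out <- vapply(sp, function(cc) {
    classify_physician_uncertainty(cc[1], cc[2], cut)
  }, character(1))
  out
}

#' Partition case reviews by AI and physician uncertainty
#'
#' @param ratings Ratings data.frame.
#' @param ai_uncertainty Named (`case_id`) `"high"`/`"low"` vector from
#'   [classify_ai_uncertainty()].
#' @param physician_uncertainty Named (`case_id`) vector from
#'   [case_physician_uncertainty()].
#' @return Named list of case-id vectors: `ai_low`, `ai_high`,
#'   `physician_low`, `physician_high` (empty subgroups trigger a warning).
#' @export
subgroup_stratify <- function(ratings, ai_uncertainty,
                              physician_uncertainty) {
  cases <- unique(ratings$case_id)
  subgroups <- list(
    ai_low = cases[ai_uncertainty[cases] == "low"],
    ai_high = cases[ai_uncertainty[cases] == "high"],
    physician_low = cases[physician_uncertainty[cases] == "low"],
    physician_high = cases[physician_uncertainty[cases] == "high"]
  )
  for (nm in names(subgroups)) {
    if (length(subgroups[[nm]]) == 0) {
      warning(sprintf("subgroup '%s' is empty", nm))
    }
  }
  subgroups
}

#' Run the MRMC comparison within each uncertainty subgroup
#'
#' Readers whose case subset within a subgroup lacks both classes (or
#' subgroups that are empty) are skipped with a warning rather than an
#' error.
#'
#' @param ratings Ratings data.frame.
#' @param labels Named label vector or data.frame.
#' @param subgroups Named list of case-id vectors from
#'   [subgroup_stratify()].
#' @return Named list of `mrmc_result` (or `NULL` where skipped), with an
#'   `n_cases` attribute per subgroup.
#' @export
mrmc_by_subgroup <- function(ratings, labels, subgroups) {
  out <- list()
  for (nm in names(subgroups)) {
    ids <- subgroups[[nm]]
    sub <- ratings[ratings$case_id %in% ids, , drop = FALSE]
    res <- tryCatch(or_mrmc_compare(sub, labels),
                    error = function(e) {
                      warning(sprintf("subgroup '%s' skipped: %s", nm,
                                      conditionMessage(e)))
                      NULL
                    })
    if (!is.null(res)) attr(res, "n_cases") <- length(ids)
    out[nm] <- list(res)
  }
  out
}
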