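# Permutation-sampling Shapley attribution for grouped features.
#
# Exact Shapley values are exponential in the number of players; the
# permutation estimator walks random orderings of feature groups, replacing
# absent groups with values from a background case, and averages marginal
# contributions. One-hot blocks of a categorical variable are grouped as a
# single player, matching how variables are reported.

#' Permutation-sampling Shapley attributions
#'
#' For each explained row, absent feature groups are masked with the values
#' of a randomly drawn background row; the marginal contribution of each
#' group is averaged over `n_permutations` random orderings. Attributions
#' satisfy local additivity: their sum equals the prediction minus the mean
#' background prediction, up to Monte-Carlo error.
#'
#' @param predict_fn Function taking a feature matrix and returning a numeric
#'   prediction per row.
#' @param x Feature matrix of rows to explain.
#' @param background Background feature matrix (marginal reference).
#' @param groups Named list of column-index vectors, one per feature group.
#' @param n_permutations Random orderings per explained row (>= 1).
#' @param seed Seed; also used for any stochasticity inside `predict_fn` if
#'   the caller fixes it there.
#' @return A list with `attributions` (rows x groups matrix) and `baseline`
#'   (mean background prediction).
#' @export
shapley_attributions <- function(predict_fn, x, background, groups,
                                 n_permutations = 20L, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (nrow(background) == 0) stop("background set must be nonempty")
  m <- length(groups)
  with_seed(seed, {
    baseline <- mean(predict_fn(background))
    attr_mat <- matrix(0, nrow(x), m, dimnames = list(NULL, names(groups)))
    for (i in seq_len(nrow(x))) {
      xi <- x[i, ]
      acc <- numeric(m)
      for (p in seq_len(n_permutations)) {
        perm <- sample.int(m)
        bg <- background[sample.int(nrow(background), 1), ]
        # build the sequence of hybrids: start from background, add groups
        # one at a time in permutation order; m+1 rows per permutation.
        hybrids <- matrix(rep(bg, m + 1), nrow = m + 1, byrow = TRUE)
        cur <- bg
        for (k in seq_len(m)) {
          cols <- groups[[perm[k]]]
          cur[cols] <- xi[cols]
          hybrids[k + 1, ] <- cur
        }
        colnames(hybrids) <- colnames(x)
        vals <- predict_fn(hybrids)
        acc[perm] <- acc[perm] + diff(vals)
      }
      attr_mat[i, ] <- acc / n_permutations
    }
    list(attributions = attr_mat, baseline = baseline)
  })
}

#' Global feature importance as mean absolute Shapley attribution
#'
#' Applies [shapley_attributions()] to a set of cases against a fixed
#' background subsample of the model's posterior-mean prediction, grouping
#' one-hot blocks and treating every vocabulary token as its own group, and
#' averages absolute per-case attributions into a global ranking. The
#' Monte-Carlo prediction inside the value function uses a fixed seed so
#' Shapley noise is decoupled from posterior noise.
#'
#' @param model A [train_bnn()] fit.
#' @param cases Cases to explain.
#' @param background Background cases (defaults to `cases`).
#' @param n_permutations Permutations per case.
#' @param n_background Background subsample size.
#' @param seed Seed.
#' @return A data.frame (`feature`, `importance`) sorted by decreasing
#'   importance.
#' @export
shapley_global_importance <- function(model, cases, background = cases,
                                      n_permutations = 10L,
                                      n_background = 25L, seed = 1L) {
  stopifnot(inherits(model, "trained_bnn"))
  feats <- build_features(cases, model$scaler, model$tfidf, model$config,
                          model$schema)
  bg_feats <- build_features(background, model$scaler, model$tfidf,
                             model$config, model$schema)
  x <- cbind(feats$xs, feats$xt)
  bg <- cbind(bg_feats$xs, bg_feats$xt)
  bg <- with_seed(seed + 1L,
                  bg[sample.int(nrow(bg), min(n_background, nrow(bg))), ,
                     drop = FALSE])
  ds <- ncol(feats$xs)
  groups <- structured_feature_groups(model$schema)
  groups <- lapply(groups, as.integer)
  for (j in seq_along(model$tfidf$vocabulary)) {
    groups[[paste0("token:", model$tfidf$vocabulary[j])]] <- ds + j
  }
  predict_fn <- function(mat) {
    xs <- mat[, seq_len(ds), drop = FALSE]
    xt <- mat[, ds + seq_len(ncol(mat) - ds), drop = FALSE]
    predict_features(model, xs, xt,
                     n_samples = model$config$n_predict_samples,
                     seed = 12345L)$mean
  }
  res <- shapley_attributions(predict_fn, x, bg, groups,
                              n_permutations = n_permutations, seed = seed)
  imp <- colMeans(abs(res$attributions))
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out[order(-out$importance), , drop = FALSE]
}
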