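# Two-branch variational Bayesian neural network.
#
# Mean-field Gaussian variational posteriors over all weights and biases,
# N(0, prior_sd^2) priors, trained by stochastic gradient ascent on the ELBO
# with the reparameterization trick (one weight draw per minibatch) and Adam.
# The structured branch (default 100 hidden nodes) and the TF-IDF text branch
# (default 15 nodes) are concatenated into a single sigmoid output node.
# Predictions are Monte-Carlo: repeated weight draws give a per-case mean,
# SD, and a normal-approximation 95% interval on the probability scale.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) stats::plogis(x)

#' Configuration for the Bayesian neural network
#'
#' @param structured_hidden Hidden nodes of the structured branch.
#' @param text_hidden Hidden nodes of the text (TF-IDF) branch.
#' @param prior_sd SD of the mean-zero Gaussian weight prior.
#' @param lr Adam learning rate.
#' @param lr_decay Multiplicative decay applied to `lr` for the tail of
#'   training (reduces the variance of the final variational state).
#' @param lr_decay_at Fraction of epochs after which the decay applies.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param kl_weight Weight on the KL term (scaled by 1/N, linearly warmed up
#'   over the first `kl_anneal_frac` of epochs).
#' @param kl_anneal_frac Fraction of epochs for linear KL warm-up.
#' @param n_predict_samples Monte-Carlo draws per prediction (default 25).
#' @param z_for_ci Normal quantile for the predictive interval (1.96).
#' @param tuning_split Fraction of development data used for training during
#'   hyperparameter tuning (remainder is the validation fold).
#' @param grid List of hyperparameter override lists tried during tuning
#'   (selection metric: validation AUC). A single entry skips the tuning
#'   stage.
#' @param model_kind One of `"full"`, `"structured_only"`, `"text_only"`.
#' @param min_df Minimum document frequency for the TF-IDF vocabulary.
#' @param stopwords,lemmatizer Passed to [tokenize_note()].
#' @param flipout Reserved flag; both settings use the same unbiased
#'   reparameterization estimator.
#' @param seed Integer seed controlling all training randomness.
#' @return A list of class `bnn_config`.
#' @export
bnn_config <- function(structured_hidden = 100L, text_hidden = 15L,
                       prior_sd = 1, lr = 0.01, lr_decay = 0.2,
                       lr_decay_at = 0.7, epochs = 40L,
                       batch_size = 256L, kl_weight = 1,
                       kl_anneal_frac = 0.25, n_predict_samples = 25L,
                       z_for_ci = 1.96, tuning_split = 0.8,
                       grid = list(list(lr = 0.01), list(lr = 0.003)),
                       model_kind = c("full", "structured_only", "text_only"),
                       min_df = 0.01, stopwords = character(),
                       lemmatizer = identity, flipout = FALSE, seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(structured_hidden >= 1, text_hidden >= 1,
            n_predict_samples >= 2, tuning_split > 0, tuning_split < 1)
  structure(list(structured_hidden = as.integer(structured_hidden),
                 text_hidden = as.integer(text_hidden), prior_sd = prior_sd,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), kl_weight = kl_weight,
                 kl_anneal_frac = kl_anneal_frac,
                 lr_decay = lr_decay, lr_decay_at = lr_decay_at,
                 n_predict_samples = as.integer(n_predict_samples),
                 z_for_ci = z_for_ci, tuning_split = tuning_split,
                 grid = grid, model_kind = model_kind, min_df = min_df,
                 stopwords = stopwords, lemmatizer = lemmatizer,
                 flipout = isTRUE(flipout), seed = as.integer(seed)),
            class = "bnn_config")
}

#' Resolve an ablation architecture
#'
#' `structured_only` keeps only the structured branch, `text_only` only the
#' TF-IDF branch, `full` concatenates both before the output node.
#'
#' @param model_kind Architecture kind.
#' @param config A [bnn_config()].
#' @return A list describing which branches are active and their widths.
#' @export
build_ablation <- function(model_kind = c("full", "structured_only",
                                          "text_only"),
                           config = bnn_config()) {
  model_kind <- match.arg(model_kind)
  list(kind = model_kind,
       use_structured = model_kind != "text_only",
       use_text = model_kind != "structured_only",
       structured_hidden = if (model_kind != "text_only")
         config$structured_hidden else 0L,
       text_hidden = if (model_kind != "structured_only")
         config$text_hidden else 0L)
}

# ---- variational parameter tensors ---------------------------------------

new_vparam <- function(nr, nc, fan_in, rho0 = -3) {
  list(mu = matrix(stats::rnorm(nr * nc, 0, sqrt(2 / max(1, fan_in))),
                   nr, nc),
       rho = matrix(rho0, nr, nc))
}

init_params <- function(d_struct, d_text, arch) {
  params <- list()
  concat <- 0L
  if (arch$use_structured) {
    params$Ws <- new_vparam(d_struct, arch$structured_hidden, d_struct)
    params$bs <- new_vparam(1, arch$structured_hidden, 1)
    concat <- concat + arch$structured_hidden
  }
  if (arch$use_text) {
    params$Wt <- new_vparam(d_text, arch$text_hidden, d_text)
    params$bt <- new_vparam(1, arch$text_hidden, 1)
    concat <- concat + arch$text_hidden
  }
  params$Wo <- new_vparam(concat, 1, concat)
  params$bo <- new_vparam(1, 1, 1)
  params
}

sample_eps <- function(params) {
  lapply(params, function(p) {
    matrix(stats::rnorm(length(p$mu)), nrow(p$mu), ncol(p$mu))
  })
}

realize_weights <- function(params, eps) {
  w <- list()
  for (nm in names(params)) {
    sg <- softplus(params[[nm]]$rho)
    w[[nm]] <- params[[nm]]$mu + sg * eps[[nm]]
  }
  w
}

# KL( N(mu, sigma^2) || N(0, prior_sd^2) ), summed over every weight/bias.
kl_divergence <- function(params, prior_sd = 1) {
  total <- 0
  for (p in params) {
    sg <- softplus(p$rho)
    total <- total +
      sum(log(prior_sd / sg) + (sg^2 + p$mu^2) / (2 * prior_sd^2) - 0.5)
  }
  total
}

# Forward pass with realized weights; returns logits and activation cache.
forward_logits <- function(w, xs, xt, arch) {
  h <- NULL
  cache <- list()
  if (arch$use_structured) {
    z1s <- xs %*% w$Ws + matrix(w$bs, nrow(xs), length(w$bs), byrow = TRUE)
    hs <- pmax(z1s, 0)
    cache$z1s <- z1s
    h <- hs
  }
  if (arch$use_text) {
    z1t <- xt %*% w$Wt + matrix(w$bt, nrow(xt), length(w$bt), byrow = TRUE)
    ht <- pmax(z1t, 0)
    cache$z1t <- z1t
    h <- if (is.null(h)) ht else cbind(h, ht)
  }
  cache$h <- h
  cache$z <- drop(h %*% w$Wo) + drop(w$bo)
  cache
}

# Numerically stable mean binary cross-entropy from logits.
bce_from_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Monte-Carlo estimate of the negative ELBO
#'
#' Returns the per-example negative ELBO estimate: mean binary cross-entropy
#' under `n_samples` weight draws plus `kl_weight * KL / n_train`.
#'
#' @param model A trained model (or a bare list with `params`, `arch`,
#'   `config`).
#' @param xs,xt Structured / text feature matrices (either may be `NULL` for
#'   ablation architectures).
#' @param y Binary labels.
#' @param kl_weight KL weight.
#' @param n_train Dataset size used to scale the KL term.
#' @param n_samples Number of Monte-Carlo weight draws.
#' @param seed Optional seed.
#' @return List with `loss`, `nll`, `kl`, and the Monte-Carlo standard error
#'   `se` of the `nll` component.
#' @export
bnn_elbo <- function(model, xs, xt, y, kl_weight = 1, n_train = length(y),
                     n_samples = 1L, seed = NULL) {
  run <- function() {
    nlls <- vapply(seq_len(n_samples), function(s) {
      eps <- sample_eps(model$params)
      w <- flatten_weights(realize_weights(model$params, eps))
      cache <- forward_logits(w, xs, xt, model$arch)
      bce_from_logits(cache$z, y)
    }, numeric(1))
    kl <- kl_divergence(model$params, model$config$prior_sd)
    loss <- mean(nlls) + kl_weight * kl / n_train
    if (!is.finite(loss)) stop("non-finite ELBO estimate")
    list(loss = loss, nll = mean(nlls), kl = kl,
         se = if (n_samples > 1) stats::sd(nlls) / sqrt(n_samples) else NA_real_)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# realize_weights returns per-tensor matrices already; biases must be plain
# vectors for forward_logits.
flatten_weights <- function(w) {
  list(Ws = w$Ws, bs = if (!is.null(w$bs)) drop(w$bs) else NULL,
       Wt = w$Wt, bt = if (!is.null(w$bt)) drop(w$bt) else NULL,
       Wo = w$Wo, bo = drop(w$bo))
}

# ---- training -------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(
    m_mu = p$mu * 0, v_mu = p$mu * 0, m_rho = p$rho * 0, v_rho = p$rho * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    for (fld in c("mu", "rho")) {
      g <- grads[[nm]][[fld]]
      mk <- paste0("m_", fld); vk <- paste0("v_", fld)
      state[[nm]][[mk]] <- beta1 * state[[nm]][[mk]] + (1 - beta1) * g
      state[[nm]][[vk]] <- beta2 * state[[nm]][[vk]] + (1 - beta2) * g^2
      mhat <- state[[nm]][[mk]] / (1 - beta1^t)
      vhat <- state[[nm]][[vk]] / (1 - beta2^t)
      params[[nm]][[fld]] <- params[[nm]][[fld]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# One minibatch: sample weights, forward, manual backprop through the
# reparameterization, returning gradients w.r.t. every (mu, rho).
batch_gradients <- function(params, eps, xs, xt, y, arch, klw_over_n,
                            prior_sd) {
  w <- flatten_weights(realize_weights(params, eps))
  cache <- forward_logits(w, xs, xt, arch)
  b <- length(y)
  p <- sigmoid(cache$z)
  dz <- matrix((p - y) / b, ncol = 1)
  grads <- list()
  # output layer
  dWo <- crossprod(cache$h, dz)
  dbo <- matrix(sum(dz), 1, 1)
  dh <- dz %*% t(w$Wo)                        # B x concat
  col0 <- 0L
  dW_list <- list(Wo = dWo, bo = dbo)
  if (arch$use_structured) {
    cols <- col0 + seq_len(arch$structured_hidden)
    dz1s <- dh[, cols, drop = FALSE] * (cache$z1s > 0)
    dW_list$Ws <- crossprod(xs, dz1s)
    dW_list$bs <- matrix(colSums(dz1s), 1)
    col0 <- col0 + arch$structured_hidden
  }
  if (arch$use_text) {
    cols <- col0 + seq_len(arch$text_hidden)
    dz1t <- dh[, cols, drop = FALSE] * (cache$z1t > 0)
    dW_list$Wt <- crossprod(xt, dz1t)
    dW_list$bt <- matrix(colSums(dz1t), 1)
  }
  for (nm in names(params)) {
    sg <- softplus(params[[nm]]$rho)
    dsg_drho <- sigmoid(params[[nm]]$rho)
    dW <- dW_list[[nm]]
    g_mu <- dW + klw_over_n * params[[nm]]$mu / prior_sd^2
    g_rho <- dW * eps[[nm]] * dsg_drho +
      klw_over_n * (sg / prior_sd^2 - 1 / sg) * dsg_drho
    grads[[nm]] <- list(mu = g_mu, rho = g_rho)
  }
  nll <- bce_from_logits(cache$z, y)
  list(grads = grads, nll = nll,
       loss = nll + klw_over_n * kl_divergence(params, prior_sd))
}

# Core SGD loop on already-built feature matrices. Deterministic given the
# caller's RNG state.
fit_bnn_core <- function(xs, xt, y, arch, config) {
  d_struct <- if (arch$use_structured) ncol(xs) else 0L
  d_text <- if (arch$use_text) ncol(xt) else 0L
  params <- init_params(d_struct, d_text, arch)
  state <- adam_init(params)
  n <- length(y)
  anneal_epochs <- max(1, ceiling(config$kl_anneal_frac * config$epochs))
  history <- numeric(config$epochs)
  t_step <- 0
  for (epoch in seq_len(config$epochs)) {
    klw <- config$kl_weight * min(1, epoch / anneal_epochs)
    lr_e <- config$lr *
      if (epoch > config$lr_decay_at * config$epochs) config$lr_decay else 1
    idx <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      bi <- idx[s:min(s + config$batch_size - 1, n)]
      eps <- sample_eps(params)
      bg <- batch_gradients(params,
                            eps,
                            if (arch$use_structured) xs[bi, , drop = FALSE],
                            if (arch$use_text) xt[bi, , drop = FALSE],
                            y[bi], arch, klw / n, config$prior_sd)
      if (!is.finite(bg$loss)) stop("training diverged: non-finite ELBO")
      t_step <- t_step + 1
      upd <- adam_step(params, bg$grads, state, lr_e, t_step)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bg$nll * length(bi)
    }
    # history records the full-weight objective (annealing only shapes the
    # optimization path, not the reported ELBO)
    history[epoch] <- ep_loss / n +
      config$kl_weight * kl_divergence(params, config$prior_sd) / n
  }
  list(params = params, history = history)
}

# ---- user-facing train / predict -----------------------------------------

build_features <- function(cases, scaler, tfidf, config, schema) {
  xs <- transform_structured(cases, scaler, schema)
  toks <- tokenize_note(cases$note, config$stopwords, config$lemmatizer)
  if (!is.list(toks)) toks <- list(toks)
  xt <- transform_tfidf(toks, tfidf)
  list(xs = xs, xt = xt)
}

#' Train the Bayesian bacteremia model on a development cohort
#'
#' Two-stage protocol: (1) if the config grid has more than one entry, split
#' the development data into training/validation folds (`tuning_split`), fit
#' preprocessing on the training fold only, train each candidate, and select
#' by validation AUC; (2) refit preprocessing and the network on 100% of the
#' development data with the selected hyperparameters. Deterministic given
#' `config$seed`.
#'
#' @param cases Development cohort data.frame with `label` and `note`.
#' @param config A [bnn_config()].
#' @return A `trained_bnn`: variational parameters, architecture, fitted
#'   scaler and TF-IDF model, training history (ELBO per epoch), and the
#'   selected hyperparameters.
#' @export
train_bnn <- function(cases, config = bnn_config()) {
  stopifnot(inherits(config, "bnn_config"))
  y <- cases$label
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class")
  }
  schema <- structured_schema()
  arch <- build_ablation(config$model_kind, config)
  with_seed(config$seed, {
    best <- config
    tuning <- NULL
    if (length(config$grid) > 1) {
      n <- nrow(cases)
      tr_idx <- sample.int(n, floor(config$tuning_split * n))
      tr <- cases[tr_idx, , drop = FALSE]
      va <- cases[-tr_idx, , drop = FALSE]
      scaler <- fit_structured(tr, schema)
      toks <- tokenize_note(tr$note, config$stopwords, config$lemmatizer)
      if (!is.list(toks)) toks <- list(toks)
      tfidf <- fit_tfidf(toks, config$min_df)
      ftr <- build_features(tr, scaler, tfidf, config, schema)
      fva <- build_features(va, scaler, tfidf, config, schema)
      val_auc <- vapply(config$grid, function(ov) {
        cand <- utils::modifyList(config, ov)
        fit <- fit_bnn_core(ftr$xs, ftr$xt, tr$label, arch, cand)
        pred <- predict_features(list(params = fit$params, arch = arch,
                                      config = cand),
                                 fva$xs, fva$xt,
                                 n_samples = cand$n_predict_samples)
        roc_auc_delong(pred$mean, va$label)$auc
      }, numeric(1))
      best <- utils::modifyList(config, config$grid[[which.max(val_auc)]])
      tuning <- data.frame(candidate = seq_along(config$grid),
                           val_auc = val_auc)
    }
    scaler <- fit_structured(cases, schema)
    toks <- tokenize_note(cases$note, config$stopwords, config$lemmatizer)
    if (!is.list(toks)) toks <- list(toks)
    tfidf <- fit_tfidf(toks, config$min_df)
    feats <- build_features(cases, scaler, tfidf, config, schema)
    fit <- fit_bnn_core(feats$xs, feats$xt, y, arch, best)
    structure(list(params = fit$params, arch = arch, config = best,
                   scaler = scaler, tfidf = tfidf, schema = schema,
                   history = fit$history, tuning = tuning,
                   d_struct = ncol(feats$xs), d_text = ncol(feats$xt)),
              class = "trained_bnn")
  })
}

# Monte-Carlo predictive distribution on prepared feature matrices.
predict_features <- function(model, xs, xt, n_samples = 25L, seed = NULL,
                             z = NULL) {
  stopifnot(n_samples >= 2)
  z <- z %||% (model$config$z_for_ci %||% 1.96)
  run <- function() {
    n <- if (model$arch$use_structured) nrow(xs) else nrow(xt)
    draws <- matrix(0, n, n_samples)
    for (s in seq_len(n_samples)) {
      eps <- sample_eps(model$params)
      w <- flatten_weights(realize_weights(model$params, eps))
      draws[, s] <- sigmoid(forward_logits(w, xs, xt, model$arch)$z)
    }
    m <- rowMeans(draws)
    sd_ <- apply(draws, 1, stats::sd)
    data.frame(mean = m, sd = sd_,
               ci_low = pmax(0, m - z * sd_),
               ci_high = pmin(1, m + z * sd_),
               n_samples = n_samples)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Posterior predictive summaries for new cases
#'
#' Draws `n_samples` weight realizations, passes the cases through the
#' network, and summarizes the sigmoid outputs per case: Monte-Carlo mean
#' (the point prediction), sample SD, and the clipped normal-approximation
#' 95% interval `mean +/- z * sd`.
#'
#' @param model A [train_bnn()] fit.
#' @param cases Cohort data.frame (raw; preprocessing is applied with the
#'   model's fitted statistics).
#' @param n_samples Monte-Carlo draws (default from the config, 25).
#' @param seed Seed for the weight draws.
#' @return A data.frame with columns `case_id` (if present), `mean`, `sd`,
#'   `ci_low`, `ci_high`, `n_samples`.
#' @export
predict_bnn <- function(model, cases, n_samples = NULL, seed = 1L) {
  stopifnot(inherits(model, "trained_bnn"))
  n_samples <- n_samples %||% model$config$n_predict_samples
  feats <- build_features(cases, model$scaler, model$tfidf, model$config,
                          model$schema)
  if (ncol(feats$xs) != model$d_struct || ncol(feats$xt) != model$d_text) {
    stop("feature dimension mismatch between cases and trained model")
  }
  out <- predict_features(model, feats$xs, feats$xt, n_samples, seed = seed)
  if (!is.null(cases$case_id)) out <- cbind(case_id = cases$case_id, out)
  out
}

#' Construct posterior-prediction summaries directly
#'
#' Builds the same per-case summary structure that [predict_bnn()] returns
#' from externally supplied means and SDs (e.g., a synthetic AI with known
#' discrimination in reader-study simulations).
#'
#' @param mean Point predictions (probabilities).
#' @param sd Probability-scale Monte-Carlo SDs.
#' @param case_id Optional case identifiers.
#' @param n_samples Nominal sample count.
#' @param z Normal quantile for the interval.
#' @return A data.frame with `mean`, `sd`, `ci_low`, `ci_high`, `n_samples`.
#' @export
make_posterior_prediction <- function(mean, sd, case_id = NULL,
                                      n_samples = 25L, z = 1.96) {
  stop_if_not_prob(mean, "mean")
  stopifnot(all(sd >= 0))
  out <- data.frame(mean = mean, sd = sd,
                    ci_low = pmax(0, mean - z * sd),
                    ci_high = pmin(1, mean + z * sd),
                    n_samples = n_samples)
  if (!is.null(case_id)) out <- cbind(case_id = case_id, out)
  out
}
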