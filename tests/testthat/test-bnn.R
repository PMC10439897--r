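# Variational Bayesian network: ELBO correctness, training behaviour, and
# the Monte-Carlo predictive distribution.

# hand-built tiny model: structured branch only, one hidden node
tiny_model <- function(mu_ws, mu_bs, mu_wo, mu_bo, sd_w = 1e-12) {
  rho <- function(s) log(expm1(s))
  cfg <- bnn_config(structured_hidden = 1, model_kind = "structured_only",
                    grid = list(list()))
  arch <- build_ablation("structured_only", cfg)
  params <- list(
    Ws = list(mu = matrix(mu_ws, 1, 1), rho = matrix(rho(sd_w), 1, 1)),
    bs = list(mu = matrix(mu_bs, 1, 1), rho = matrix(rho(sd_w), 1, 1)),
    Wo = list(mu = matrix(mu_wo, 1, 1), rho = matrix(rho(sd_w), 1, 1)),
    bo = list(mu = matrix(mu_bo, 1, 1), rho = matrix(rho(sd_w), 1, 1)))
  list(params = params, arch = arch, config = cfg)
}

test_that("point-mass posterior reduces the ELBO to deterministic cross-entropy", {
  m <- tiny_model(0.8, -0.2, 1.5, -1)
  xs <- matrix(c(-1, 0.5, 2), ncol = 1)
  y <- c(0, 1, 1)
  z <- pmax(xs %*% matrix(0.8) - 0.2, 0) * 1.5 - 1
  bce <- mean(-y * log(plogis(z)) - (1 - y) * log(1 - plogis(z)))
  e <- bnn_elbo(m, xs, NULL, y, kl_weight = 0, n_samples = 3, seed = 1)
  expect_equal(e$loss, bce, tolerance = 1e-9)
})

test_that("KL vanishes when the variational posterior equals the prior", {
  rho1 <- log(expm1(1))
  params <- list(w = list(mu = matrix(0, 3, 2),
                          rho = matrix(rho1, 3, 2)))
  expect_lt(abs(bacterisk:::kl_divergence(params, prior_sd = 1)), 1e-12)
  # and the closed form is positive away from the prior
  params$w$mu[1, 1] <- 1
  expect_gt(bacterisk:::kl_divergence(params, prior_sd = 1), 0.4)
})

test_that("MC ELBO matches a 2-D quadrature oracle on a 2-weight network", {
  m <- tiny_model(0.6, 0.3, -0.9, 0.2)
  # free weights: Ws and Wo with sd 0.5; biases stay point masses
  m$params$Ws$rho <- matrix(log(expm1(0.5)), 1, 1)
  m$params$Wo$rho <- matrix(log(expm1(0.5)), 1, 1)
  xs <- matrix(c(-1.2, 0.4, 1.7), ncol = 1)
  y <- c(0, 1, 0)
  # grid quadrature over (w1, w2)
  gw <- function(mu, sd) {
    g <- seq(mu - 8 * sd, mu + 8 * sd, length.out = 801)
    list(x = g, w = dnorm(g, mu, sd) * (g[2] - g[1]))
  }
  q1 <- gw(0.6, 0.5); q2 <- gw(-0.9, 0.5)
  h <- pmax(outer(drop(xs), q1$x) + 0.3, 0)       # 3 x 801
  oracle <- 0
  for (j in seq_along(q2$x)) {
    z <- h * q2$x[j] + 0.2
    bce <- colMeans(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
    oracle <- oracle + sum(bce * q1$w) * q2$w[j]
  }
  e <- bnn_elbo(m, xs, NULL, y, kl_weight = 0, n_samples = 100000, seed = 2)
  expect_lt(abs(e$loss - oracle), 3 * e$se)
})

test_that("training is deterministic given the seed", {
  co <- tiny_cohort(300, seed = 71)
  cfg <- bnn_config(epochs = 4, grid = list(list(lr = 0.01)), seed = 5)
  m1 <- train_bnn(co, cfg)
  m2 <- train_bnn(co, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_error(train_bnn(transform(co, label = 1), cfg), "single class")
})

test_that("linearly separable data is learned nearly perfectly", {
  co <- tiny_cohort(2000, seed = 72)
  co$label <- as.integer(co$bt > 37.4)
  m <- train_bnn(co, bnn_config(epochs = 40, grid = list(list(lr = 0.01)),
                                seed = 6))
  p <- predict_bnn(m, co, seed = 7)
  expect_gt(roc_auc_delong(p$mean, co$label)$auc, 0.95)
})

test_that("the ELBO trajectory decreases on a smoothed basis", {
  co <- tiny_cohort(1500, seed = 73)
  m <- train_bnn(co, bnn_config(epochs = 30, grid = list(list(lr = 0.01)),
                                seed = 8))
  ma <- stats::filter(m$history, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 0.02))
  expect_lt(ma[length(ma)], ma[1])
})

test_that("point-mass posterior predicts with zero spread; CIs are ordered", {
  m <- tiny_model(0.5, 0, 1, -2)
  xs <- matrix(rnorm(20), ncol = 1)
  p <- bacterisk:::predict_features(m, xs, NULL, n_samples = 25, seed = 3)
  expect_true(all(abs(p$sd) < 1e-9))
  expect_equal(p$ci_low, p$mean, tolerance = 1e-8)
  co <- generate_cohort(cohort_spec(n_cases = 10000, seed = 74))
  mt <- train_bnn(tiny_cohort(400, seed = 75),
                  bnn_config(epochs = 3, grid = list(list(lr = 0.01)),
                             seed = 9))
  pr <- predict_bnn(mt, co, seed = 10)
  expect_true(all(pr$ci_low >= 0 & pr$ci_low <= pr$mean))
  expect_true(all(pr$mean <= pr$ci_high & pr$ci_high <= 1))
})

test_that("Monte-Carlo means follow the 1/sqrt(n) standard-error law", {
  mt <- train_bnn(tiny_cohort(400, seed = 76),
                  bnn_config(epochs = 10, grid = list(list(lr = 0.01)),
                             seed = 11))
  case <- tiny_cohort(400, seed = 76)[5, , drop = FALSE]
  big <- predict_bnn(mt, case, n_samples = 4000, seed = 12)
  sigma1 <- big$sd                         # per-draw SD, well estimated
  means25 <- vapply(1:150, function(s) {
    predict_bnn(mt, case, n_samples = 25, seed = 1000 + s)$mean
  }, numeric(1))
  ratio <- sd(means25) / (sigma1 / sqrt(25))
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("ablation architectures drop the intended branch", {
  co <- tiny_cohort(300, seed = 77)
  cfg <- bnn_config(epochs = 2, grid = list(list(lr = 0.01)), seed = 13)
  ms <- train_bnn(co, utils::modifyList(cfg, list(model_kind = "structured_only")))
  expect_null(ms$params$Wt)
  expect_equal(nrow(ms$params$Wo$mu), 100)
  mt <- train_bnn(co, utils::modifyList(cfg, list(model_kind = "text_only")))
  expect_null(mt$params$Ws)
  expect_equal(nrow(mt$params$Wo$mu), 15)
  expect_error(build_ablation("bogus"), "arg")
})

test_that("a text-only model recovers the planted token signal", {
  co <- tiny_cohort(4000, seed = 78)
  dev <- co[1:3000, ]; test <- co[3001:4000, ]
  m <- train_bnn(dev, bnn_config(epochs = 60, grid = list(list(lr = 0.01)),
                                 seed = 14, model_kind = "text_only"))
  p <- predict_bnn(m, test, seed = 15)
  r <- roc_auc_delong(p$mean, test$label)
  expect_gt(r$auc, 0.5 + 5 * sqrt(r$variance))
})
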