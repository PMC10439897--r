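# DeLong AUC machinery, threshold metrics, calibration tables.

test_that("AUC handles separation and complete ties", {
  expect_equal(roc_auc_delong(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc_delong(c(0.5, 0.5), c(1, 0))$auc, 0.5)
  expect_error(roc_auc_delong(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC equals brute-force concordance on random tied data", {
  withr::with_seed(11, {
    for (i in 1:25) {
      n <- sample(6:30, 1)
      scores <- sample(1:5, n, replace = TRUE)  # heavy ties
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      expect_identical(roc_auc_delong(scores, labels)$auc,
                       brute_auc(scores, labels))
    }
  })
})

test_that("DeLong variance agrees with pROC's implementation", {
  withr::with_seed(12, {
    scores <- rnorm(150)
    labels <- rbinom(150, 1, plogis(scores))
    r <- roc_auc_delong(scores, labels)
    pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$variance, pROC::var(pr), tolerance = 1e-10)
  })
})

test_that("AUC complement and monotone-transform invariances hold", {
  withr::with_seed(13, {
    scores <- c(rnorm(40), rnorm(10) + 1)
    labels <- rep(c(0, 1), c(40, 10))
    a1 <- roc_auc_delong(scores, labels)$auc
    a2 <- roc_auc_delong(-scores, labels)$auc
    expect_identical(a1 + a2, 1)
    expect_identical(roc_auc_delong(exp(scores) * 3 + 2, labels)$auc, a1)
  })
})

test_that("roc_curve trapezoid area reproduces the AUC", {
  withr::with_seed(14, {
    scores <- sample(1:5, 60, replace = TRUE)
    labels <- rbinom(60, 1, 0.3)
    cv <- roc_curve(scores, labels)
    area <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(area, roc_auc_delong(scores, labels)$auc, tolerance = 1e-12)
  })
})

test_that("confusion metrics match the hand-computed 2x2 table", {
  # TP=30 FN=10 FP=20 TN=40
  labels <- rep(c(1, 1, 0, 0), c(30, 10, 20, 40))
  pred <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 20, 40))
  m <- confusion_metrics(pred, labels)
  expect_equal(m$estimate[m$metric == "sensitivity"], 0.75)
  expect_equal(m$estimate[m$metric == "specificity"], 2 / 3)
  # Wilson formula by hand for sensitivity (30/40)
  z <- qnorm(0.975); p <- 0.75; n <- 40
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(m$ci_low[m$metric == "sensitivity"], lo, tolerance = 1e-12)
  expect_equal(unname(wilson_ci(30, 40)["lower"]),
               prop.test(30, 40, correct = FALSE)$conf.int[1],
               tolerance = 1e-10)
})

test_that("degenerate classifiers flag undefined metrics instead of crashing", {
  labels <- c(1, 1, 0, 0)
  perfect <- confusion_metrics(c(TRUE, TRUE, FALSE, FALSE), labels)
  expect_true(all(perfect$estimate == 1))
  allpos <- confusion_metrics(rep(TRUE, 4), labels)
  expect_equal(allpos$estimate[allpos$metric == "sensitivity"], 1)
  expect_equal(allpos$estimate[allpos$metric == "specificity"], 0)
  expect_true(allpos$undefined[allpos$metric == "npv"])
})

test_that("calibration table aggregates, covers, and handles single bins", {
  labels <- rep(c(1, 0), c(100, 900))
  ct <- calibration_table(rep(0.1, 1000), labels)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$observed, 0.1)
  withr::with_seed(15, {
    preds <- rbeta(5000, 1.2, 6)
    cover_frac <- vapply(1:30, function(b) {
      labs <- rbinom(5000, 1, preds)
      ct <- calibration_table(preds, labs)
      mean(ct$ci_low <= ct$predicted_mean & ct$predicted_mean <= ct$ci_high)
    }, numeric(1))
    expect_gte(mean(cover_frac), 0.9)
    expect_equal(sum(calibration_table(preds, rbinom(5000, 1, preds))$count),
                 5000)
  })
})

test_that("n_bins = 1 reduces to overall prevalence", {
  withr::with_seed(16, {
    preds <- runif(400); labs <- rbinom(400, 1, 0.25)
    ct <- calibration_table(preds, labs, n_bins = 1)
    expect_equal(ct$observed, mean(labs))
  })
})
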