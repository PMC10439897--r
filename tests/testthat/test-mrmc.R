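# Reader-study statistics: per-reader AUC, OR MRMC comparison, kappa,
# paired confidence test, transitions, ROC averaging, subgrouping.

test_that("reader AUC handles separation, ties, and matches brute force", {
  expect_equal(reader_auc(c(5, 5, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(reader_auc(rep(3, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(41, {
    for (i in 1:10) {
      bins <- sample(1:5, 40, replace = TRUE)
      labels <- c(0, 1, rbinom(38, 1, 0.3))
      expect_identical(reader_auc(bins, labels), brute_auc(bins, labels))
    }
  })
})

test_that("identical modalities give zero difference and p = 1", {
  withr::with_seed(42, {
    co <- tiny_cohort(200, seed = 43)
    ai <- synthetic_ai(co, 44)
    r <- simulate_readers(co, ai, reader_params(n_readers = 4, seed = 45))
    pre <- r[r$phase == "pre", ]
    post <- pre; post$phase <- "post"
    m <- or_mrmc_compare(rbind(pre, post),
                         stats::setNames(co$label, co$case_id))
    expect_equal(m$difference, 0)
    expect_equal(m$p_value, 1)
  })
})

test_that("MRMC AUC point estimates equal mean per-reader AUCs", {
  st <- null_reader_study(1000, seed = 46)
  m <- or_mrmc_compare(st$ratings, st$labels)
  pre <- st$ratings[st$ratings$phase == "pre", ]
  per_reader <- vapply(split(pre, pre$reader_id), function(d) {
    reader_auc(d$bin, st$labels[d$case_id])
  }, numeric(1))
  expect_equal(m$auc_pre, mean(per_reader), tolerance = 1e-12)
  expect_true(m$ci_low <= m$difference && m$difference <= m$ci_high)
})

test_that("jackknife covariance components match brute-force recomputation", {
  # 2 readers x 20 shared cases, both phases
  withr::with_seed(47, {
    labels <- c(rep(1, 6), rep(0, 14))
    case_id <- sprintf("c%02d", 1:20)
    ratings <- do.call(rbind, lapply(1:2, function(r) {
      do.call(rbind, lapply(c("pre", "post"), function(ph) {
        data.frame(case_id = case_id, reader_id = paste0("r", r), phase = ph,
                   bin = sample(1:5, 20, replace = TRUE))
      }))
    }))
    names(labels) <- case_id
    m <- or_mrmc_compare(ratings, labels)
    # brute force: recompute each leave-one-case-out AUC from scratch
    brute_jack <- function(r, ph) {
      d <- ratings[ratings$reader_id == r & ratings$phase == ph, ]
      d <- d[order(d$case_id), ]
      vapply(seq_len(20), function(k) {
        brute_auc(d$bin[-k], labels[d$case_id][-k])
      }, numeric(1))
    }
    cells <- list(brute_jack("r1", "pre"), brute_jack("r1", "post"),
                  brute_jack("r2", "pre"), brute_jack("r2", "post"))
    jcov <- function(a, b) 19 / 20 * sum((a - mean(a)) * (b - mean(b)))
    var_error <- mean(vapply(cells, function(a) jcov(a, a), numeric(1)))
    cov1 <- (jcov(cells[[1]], cells[[2]]) + jcov(cells[[3]], cells[[4]])) / 2
    cov2 <- (jcov(cells[[1]], cells[[3]]) + jcov(cells[[2]], cells[[4]])) / 2
    cov3 <- (jcov(cells[[1]], cells[[4]]) + jcov(cells[[2]], cells[[3]])) / 2
    expect_equal(m$components$var_error, var_error, tolerance = 1e-10)
    expect_equal(m$components$cov1, cov1, tolerance = 1e-10)
    expect_equal(m$components$cov2, cov2, tolerance = 1e-10)
    expect_equal(m$components$cov3, cov3, tolerance = 1e-10)
  })
})

test_that("degenerate reader designs are rejected", {
  st <- null_reader_study(200, seed = 48)
  one <- st$ratings[st$ratings$reader_id == "reader_01", ]
  expect_error(or_mrmc_compare(one, st$labels), "two readers")
  missing_phase <- st$ratings[!(st$ratings$reader_id == "reader_01" &
                                  st$ratings$phase == "post"), ]
  expect_error(or_mrmc_compare(missing_phase, st$labels), "missing phase")
})

test_that("weighted kappa matches the direct contingency formula", {
  expect_equal(weighted_kappa(c(1, 3, 5, 2), c(1, 3, 5, 2)), 1)
  # 4-pair toy table, by hand
  r1 <- c(1, 1, 2, 2); r2 <- c(1, 2, 2, 2)
  expect_equal(weighted_kappa(r1, r2), brute_weighted_kappa(r1, r2),
               tolerance = 1e-15)
  withr::with_seed(49, {
    for (i in 1:20) {
      a <- sample(1:5, 60, replace = TRUE)
      b <- pmin(5, pmax(1, a + sample(-2:2, 60, replace = TRUE)))
      expect_equal(weighted_kappa(a, b), brute_weighted_kappa(a, b),
                   tolerance = 1e-12)
      expect_equal(weighted_kappa(a, b), weighted_kappa(b, a),
                   tolerance = 1e-15)
    }
  })
})

test_that("independent ratings give kappa near zero", {
  withr::with_seed(50, {
    a <- sample(1:5, 10000, replace = TRUE)
    b <- sample(1:5, 10000, replace = TRUE)
    expect_lt(abs(weighted_kappa(a, b)), 0.05)
  })
  expect_error(weighted_kappa(1, 1), "two pairs")
})

test_that("paired confidence test matches the textbook formula", {
  r <- paired_confidence_test(c(3, 3, 3), c(3, 3, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  pre <- c(2, 2, 2, 3); post <- pre + c(1, 1, 1, -1)
  r <- paired_confidence_test(pre, post)
  d <- c(1, 1, 1, -1)
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  expect_error(paired_confidence_test(1, 2), "two pairs")
  degen <- paired_confidence_test(c(1, 1), c(2, 2))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p_value))
})

test_that("transition matrices tally flows and conserve marginals", {
  pre <- c(1, 1, 2, 3, 5)
  expect_true(all(transition_matrix(pre, pre)[
    cbind(as.character(pre), as.character(pre))] > 0))
  expect_equal(sum(transition_matrix(pre, pre)), length(pre))
  g <- c(`1` = "very low", `2` = "low-high", `3` = "low-high",
         `4` = "low-high", `5` = "low-high")
  tm <- transition_matrix(c(1, 1, 2), c(2, 1, 2), g)
  expect_equal(unname(tm["very low", "low-high"]), 1)
  expect_equal(unname(tm["very low", "very low"]), 1)
  expect_equal(unname(tm["low-high", "low-high"]), 1)
  expect_equal(sum(tm), 3)
  expect_error(transition_matrix(c(1, NA), c(1, 2)), "paired")
})

test_that("ROC vertical averaging reproduces hand-computed curves", {
  a <- data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 1, 1))
  b <- data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.5, 1))
  expect_equal(average_roc(list(a)), a)
  expect_equal(average_roc(list(b, b)), b)
  avg <- average_roc(list(a, b))
  expect_equal(avg$tpr[avg$fpr == 0.5], 0.75)
  expect_equal(avg$tpr[avg$fpr == 1], 1)
})

test_that("uncertainty subgroups partition the cases", {
  st <- null_reader_study(200, seed = 51)
  cases <- unique(st$ratings$case_id)
  ai_unc <- stats::setNames(rep(c("low", "high"), length.out = 200), cases)
  phys <- case_physician_uncertainty(st$ratings)
  sg <- subgroup_stratify(st$ratings, ai_unc, phys)
  expect_equal(sort(c(sg$ai_low, sg$ai_high)), sort(cases))
  expect_equal(sort(c(sg$physician_low, sg$physician_high)), sort(cases))
  all_high <- stats::setNames(rep("high", 200), cases)
  expect_warning(subgroup_stratify(st$ratings, all_high, phys), "empty")
})
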