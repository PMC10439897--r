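# Structured preprocessing (imputation, standardization, one-hot) and the
# TF-IDF text pipeline.

test_that("two-point column standardizes symmetrically to +/- 1", {
  co <- tiny_cohort(2, seed = 1)
  co$age <- c(0, 2)
  sc <- fit_structured(co)
  expect_equal(unname(sc$mean["age"]), 1)
  expect_equal(unname(sc$scale["age"]), 1)
  x <- transform_structured(co, sc)
  expect_equal(unname(x[, "age"]), c(-1, 1))
})

test_that("constant column gets unit scale and zero features", {
  co <- tiny_cohort(10, seed = 2)
  co$bt <- 37
  sc <- fit_structured(co)
  expect_true(sc$constant["bt"])
  expect_equal(unname(sc$scale["bt"]), 1)
  expect_true(all(transform_structured(co, sc)[, "bt"] == 0))
})

test_that("standardized training columns have mean 0 and SD 1", {
  co <- tiny_cohort(1000, seed = 3)
  sc <- fit_structured(co)
  x <- transform_structured(co, sc)
  pop_sd <- function(z) sqrt(mean((z - mean(z))^2))
  for (v in c("age", "sbp", "hr")) {
    expect_lt(abs(mean(x[, v])), 1e-10)
    expect_lt(abs(pop_sd(x[, v]) - 1), 1e-10)
  }
})

test_that("imputed cells map to exactly zero and unknown levels error", {
  co <- tiny_cohort(50, seed = 4)
  sc <- fit_structured(co)
  co$sbp[3] <- NA
  x <- transform_structured(co, sc)
  expect_identical(unname(x[3, "sbp"]), 0)
  co$triage[1] <- 9L
  expect_error(transform_structured(co, sc), "triage")
})

test_that("one-hot blocks encode levels and sum to one per row", {
  co <- tiny_cohort(30, seed = 5)
  co$triage[1] <- 3L
  sc <- fit_structured(co)
  x <- transform_structured(co, sc)
  expect_equal(unname(x[1, paste0("triage=", 1:5)]), c(0, 0, 1, 0, 0))
  schema <- structured_schema()
  expected_cols <- length(schema$continuous) +
    sum(lengths(schema$categorical))
  expect_equal(ncol(x), expected_cols)
  for (v in names(schema$categorical)) {
    block <- x[, paste(v, schema$categorical[[v]], sep = "="), drop = FALSE]
    expect_true(all(rowSums(block) == 1))
  }
})

test_that("fitting is immutable: transforming new data changes no statistic", {
  co <- tiny_cohort(100, seed = 6)
  sc <- fit_structured(co)
  before <- serialize(sc, NULL)
  invisible(transform_structured(tiny_cohort(40, seed = 7), sc))
  expect_identical(serialize(sc, NULL), before)
})

test_that("tokenizer lowercases, strips punctuation, and honours plugins", {
  expect_equal(tokenize_note("Fever, CHILLS!"), c("fever", "chills"))
  expect_equal(tokenize_note("the fever", stopwords = "the"), "fever")
  lem <- function(t) ifelse(t == "vomited", "vomit", t)
  expect_equal(tokenize_note("Vomited twice.", lemmatizer = lem),
               c("vomit", "twice"))
  expect_equal(tokenize_note(""), character())
})

test_that("min-df threshold keeps df/N >= 1% with ties kept", {
  docs <- c(list(c("rare1", "common"), c("rare2", "common", "twice"),
                 c("twice", "common")),
            replicate(197, list("common")))
  m <- fit_tfidf(docs, min_df = 0.01)
  expect_true("twice" %in% m$vocabulary)    # df = 2 of 200 -> kept
  expect_false("rare1" %in% m$vocabulary)   # df = 1 of 200 -> dropped
  expect_error(fit_tfidf(list()), "empty")
})

test_that("idf and tf-idf match hand computation of the documented formula", {
  docs <- list(c("fever", "chills"), c("fever", "cough"))
  m <- fit_tfidf(docs, min_df = 0)
  expect_equal(unname(m$idf["fever"]), log(3 / 3) + 1, tolerance = 1e-15)
  expect_equal(unname(m$idf["chills"]), log(3 / 2) + 1, tolerance = 1e-15)
  # d2: tf * idf then L2 normalization, by hand
  v <- transform_tfidf(docs[[2]], m)
  raw <- c(chills = 0, cough = 1 * (log(3 / 2) + 1),
           fever = 1 * (log(3 / 3) + 1))
  expect_equal(v[1, ], raw / sqrt(sum(raw^2)), tolerance = 1e-15)
})

test_that("vocabulary order is deterministic and OOV tokens are ignored", {
  docs <- list(c("b", "a"), c("c", "a"))
  m1 <- fit_tfidf(docs, 0)
  m2 <- fit_tfidf(docs, 0)
  expect_identical(m1$vocabulary, m2$vocabulary)
  expect_identical(m1$vocabulary, sort(m1$vocabulary, method = "radix"))
  expect_true(all(transform_tfidf(c("zzz", "yyy"), m1) == 0))
  one <- transform_tfidf(c("a", "oov"), m1)
  expect_equal(unname(one[1, "a"]), 1)  # single in-vocab token -> unit vector
})
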