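# Independent oracles and small fixture builders shared across tests.

# Brute-force pairwise concordance AUC (O(n1 * n0) double loop).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Direct contingency-formula weighted kappa (independent of the package's
# vectorized implementation).
brute_weighted_kappa <- function(a, b, k = 5) {
  n <- length(a)
  o <- matrix(0, k, k)
  for (i in seq_len(n)) o[a[i], b[i]] <- o[a[i], b[i]] + 1
  o <- o / n
  ma <- rowSums(o); mb <- colSums(o)
  num <- den <- 0
  for (i in 1:k) for (j in 1:k) {
    w <- abs(i - j) / (k - 1)
    num <- num + w * o[i, j]
    den <- den + w * ma[i] * mb[j]
  }
  1 - num / den
}

# Small cohort with no missingness (convenient fixture).
tiny_cohort <- function(n, seed = 1, ...) {
  generate_cohort(cohort_spec(n_cases = n, seed = seed, missing_rate = 0, ...))
}

# Synthetic AI predictions with known discrimination: logit-normal noise
# around the generative risk plus heterogeneous Monte-Carlo SDs.
synthetic_ai <- function(cohort, seed, noise_sd = 0.55,
                         sd_range = c(0.004, 0.05)) {
  withr::with_seed(seed, {
    m <- stats::plogis(stats::qlogis(pmin(pmax(cohort$true_risk, 1e-6),
                                          1 - 1e-6)) +
                         stats::rnorm(nrow(cohort), 0, noise_sd))
    s <- stats::runif(nrow(cohort), sd_range[1], sd_range[2])
    make_posterior_prediction(m, s, case_id = cohort$case_id)
  })
}

# One null reader study: pre and post phases drawn independently from the
# same pre-AI rating distribution. Cases are allocated to the reader sets
# with label-stratified round-robin so every set holds at least a couple of
# cases of each class (a standard design constraint; the jackknife is
# undefined otherwise).
null_reader_study <- function(n_cases = 1000, seed = 1, n_sets = 10) {
  co <- generate_cohort(cohort_spec(n_cases = n_cases, seed = seed,
                                    missing_rate = 0))
  set_of <- integer(n_cases)
  set_of[co$label == 1] <- rep_len(seq_len(n_sets), sum(co$label == 1))
  set_of[co$label == 0] <- rep_len(seq_len(n_sets), sum(co$label == 0))
  co <- co[order(set_of), ]
  ai <- make_posterior_prediction(co$true_risk, rep(0.01, n_cases),
                                  case_id = co$case_id)
  r1 <- simulate_readers(co, ai, reader_params(seed = 2 * seed))
  r2 <- simulate_readers(co, ai, reader_params(seed = 2 * seed + 1))
  pre <- r1[r1$phase == "pre", ]
  post <- r2[r2$phase == "pre", ]
  post$phase <- "post"
  list(ratings = rbind(pre, post),
       labels = stats::setNames(co$label, co$case_id))
}

# Constant-weight reader params for degenerate-limit tests.
fixed_weight_params <- function(w, ...) {
  reader_params(ai_weight_fn = function(conf, unc) rep(w, length(conf)), ...)
}
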