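# Synthetic ED cohort generator.
#
# Stands in for the non-public hospital data: every case carries a known
# generative risk (a single logistic model over structured variables and note
# tokens), so Bayes-optimal discrimination is computable exactly and model
# recovery can be tested against it.

TRIAGE_LEVELS <- 1:5
MENTAL_LEVELS <- c("alert", "verbal", "pain", "unresponsive")
YESNO_LEVELS <- c("no", "yes")
SEX_LEVELS <- c("male", "female")
VITAL_VARS <- c("sbp", "dbp", "hr", "rr", "bt")
SITE_LEVELS <- c("respiratory", "abdominal", "other")

# Centres used inside the linear predictor so the calibrated intercept stays
# near the prevalence logit; they equal the marginal means the generator
# targets (urban tertiary-care ED, blood-culture population).
COHORT_CENTERS <- c(age = 62.3, sbp = 136.1, dbp = 76.5, hr = 99.6,
                    rr = 19.8, bt = 37.4)

#' Default note-token vocabulary for the synthetic cohort
#'
#' Each row is one token: its additive log-odds effect on the generative
#' bacteremia risk when the token occurs in the note, and its inclusion
#' probability per infection-site latent class (`p_other`, `p_resp`,
#' `p_abdo`), plus an additive probability bump when the structured chills
#' symptom is present (`p_chills`). Respiratory-site tokens ("sputum",
#' "cough", "dyspnea") lower risk; chills/fever history raises it; filler
#' tokens carry no risk signal but exercise the text pipeline.
#'
#' @return A data.frame with columns `token`, `effect`, `p_other`, `p_resp`,
#'   `p_abdo`, `p_chills`.
#' @export
default_vocab <- function() {
  tok <- function(token, effect, p_other, p_resp, p_abdo, p_chills = 0) {
    data.frame(token = token, effect = effect, p_other = p_other,
               p_resp = p_resp, p_abdo = p_abdo, p_chills = p_chills,
               stringsAsFactors = FALSE)
  }
  rbind(
    tok("chills",     0.90, 0.08, 0.08, 0.08, 0.55),
    tok("fever",      0.50, 0.20, 0.22, 0.20, 0.35),
    tok("rigors",     0.60, 0.02, 0.02, 0.02, 0.20),
    tok("sputum",    -0.70, 0.02, 0.55, 0.02),
    tok("cough",     -0.50, 0.05, 0.65, 0.04),
    tok("dyspnea",   -0.40, 0.08, 0.50, 0.05),
    tok("rhinorrhea",-0.30, 0.02, 0.30, 0.02),
    tok("cramping",   0.20, 0.03, 0.02, 0.40),
    tok("diarrhea",   0.10, 0.05, 0.04, 0.35),
    tok("patient",    0.00, 1.00, 1.00, 1.00),
    tok("presented",  0.00, 0.85, 0.85, 0.85),
    tok("history",    0.00, 0.70, 0.70, 0.70),
    tok("days",       0.00, 0.60, 0.60, 0.60),
    tok("pain",       0.00, 0.40, 0.30, 0.75),
    tok("mild",       0.00, 0.30, 0.30, 0.30),
    tok("denies",     0.00, 0.35, 0.35, 0.35),
    tok("reports",    0.00, 0.45, 0.45, 0.45),
    tok("onset",      0.00, 0.40, 0.40, 0.40),
    tok("exam",       0.00, 0.50, 0.50, 0.50),
    tok("stable",     0.00, 0.30, 0.30, 0.30)
  )
}

default_structured_effects <- function() {
  list(
    age = 0.022, sbp = -0.012, dbp = -0.006, hr = 0.010, rr = 0.025,
    bt = 0.55,
    sex = c(male = 0, female = 0.05),
    ambulance = c(no = 0, yes = 0.25),
    referred = c(no = 0, yes = -0.30),
    injury_visit = c(no = 0, yes = -1.00),
    triage = c(`1` = 0.50, `2` = 0.20, `3` = 0, `4` = -0.30, `5` = -0.50),
    mental_status = c(alert = 0, verbal = 0.30, pain = 0.50,
                      unresponsive = 0.70),
    chills = c(no = 0, yes = 0.50),
    vomiting = c(no = 0, yes = 0.25),
    abdominal_pain = c(no = 0, yes = 0.25)
  )
}

#' Specification of a synthetic ED cohort
#'
#' Defaults emulate the development-cohort marginals of a large urban
#' tertiary-care ED blood-culture population: mean age 62.3 (SD 15.9) years,
#' 45.1% female, bacteremia prevalence 10.9%, and under 3% missingness
#' confined to vital signs.
#'
#' @param n_cases Number of cases to generate.
#' @param target_prevalence Expected bacteremia prevalence; the intercept is
#'   root-found so the mean generative risk equals this value exactly.
#' @param age_mean,age_sd Age distribution in years.
#' @param female_frac Proportion female.
#' @param missing_rate Per-cell missingness probability for vital signs only.
#' @param vocab Token vocabulary; see [default_vocab()].
#' @param structured_effects Named list of per-variable log-odds effects
#'   (continuous: per natural unit about the cohort centre; categorical: per
#'   level).
#' @param site_probs Probabilities of the infection-site latent classes
#'   (respiratory, abdominal, other).
#' @param site_effects Log-odds risk modifier per site class.
#' @param intercept Optional fixed intercept; `NULL` (default) means
#'   auto-calibrate to `target_prevalence`.
#' @param seed Integer seed; the whole cohort is deterministic given the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 1000,
                        target_prevalence = 0.109,
                        age_mean = 62.3, age_sd = 15.9,
                        female_frac = 0.451,
                        missing_rate = 0.02,
                        vocab = default_vocab(),
                        structured_effects = default_structured_effects(),
                        site_probs = c(respiratory = 0.25, abdominal = 0.20,
                                       other = 0.55),
                        site_effects = c(respiratory = -0.35,
                                         abdominal = 0.15, other = 0),
                        intercept = NULL,
                        seed = 1L) {
  stopifnot(n_cases >= 0, length(n_cases) == 1)
  stop_if_not_prob(target_prevalence, "target_prevalence")
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("`target_prevalence` must lie strictly inside (0, 1)")
  }
  stop_if_not_prob(female_frac, "female_frac")
  stop_if_not_prob(missing_rate, "missing_rate")
  if (!all(is.finite(unlist(structured_effects))) ||
      !all(is.finite(vocab$effect)) ||
      !all(is.finite(site_effects))) {
    stop("all generative effects must be finite")
  }
  structure(list(
    n_cases = as.integer(n_cases), target_prevalence = target_prevalence,
    age_mean = age_mean, age_sd = age_sd, female_frac = female_frac,
    missing_rate = missing_rate, vocab = vocab,
    structured_effects = structured_effects,
    site_probs = site_probs / sum(site_probs), site_effects = site_effects,
    intercept = intercept, seed = as.integer(seed)
  ), class = "cohort_spec")
}

empty_cohort <- function() {
  data.frame(case_id = character(), age = numeric(), sex = character(),
             ambulance = character(), referred = character(),
             injury_visit = character(), triage = integer(),
             mental_status = character(), sbp = numeric(), dbp = numeric(),
             hr = numeric(), rr = numeric(), bt = numeric(),
             chills = character(), vomiting = character(),
             abdominal_pain = character(), site = character(),
             note = character(), true_risk = numeric(), label = integer(),
             stringsAsFactors = FALSE)
}

# Linear predictor (without intercept) of the generative logistic risk.
cohort_eta <- function(cohort, spec) {
  fx <- spec$structured_effects
  eta <- fx$age * (cohort$age - COHORT_CENTERS["age"]) +
    fx$sbp * (cohort$sbp - COHORT_CENTERS["sbp"]) +
    fx$dbp * (cohort$dbp - COHORT_CENTERS["dbp"]) +
    fx$hr * (cohort$hr - COHORT_CENTERS["hr"]) +
    fx$rr * (cohort$rr - COHORT_CENTERS["rr"]) +
    fx$bt * (cohort$bt - COHORT_CENTERS["bt"]) +
    fx$sex[cohort$sex] + fx$ambulance[cohort$ambulance] +
    fx$referred[cohort$referred] + fx$injury_visit[cohort$injury_visit] +
    fx$triage[as.character(cohort$triage)] +
    fx$mental_status[cohort$mental_status] + fx$chills[cohort$chills] +
    fx$vomiting[cohort$vomiting] + fx$abdominal_pain[cohort$abdominal_pain] +
    spec$site_effects[cohort$site]
  tok_eff <- stats::setNames(spec$vocab$effect, spec$vocab$token)
  note_eta <- vapply(cohort$note, function(nt) {
    toks <- unique(tokenize_note(nt))
    sum(tok_eff[intersect(toks, names(tok_eff))])
  }, numeric(1), USE.NAMES = FALSE)
  unname(eta + note_eta)
}

#' Generate a synthetic ED cohort with known generative risk
#'
#' Draws structured covariates from the spec's marginals, an infection-site
#' latent class, a free-text note whose token inclusion depends on the site
#' and the chills symptom, then computes the generative logistic risk
#' `plogis(intercept + effects . x + sum of token effects)` and draws the
#' bacteremia label from it. The intercept is root-found on the sampled
#' covariates so the mean risk equals `target_prevalence` (to < 1e-6).
#' Missingness at `spec$missing_rate` is then injected into vital signs.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with one row per case: structured variables, `site`
#'   latent, `note` text, exact `true_risk`, and `label` (0/1).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases
  if (n == 0) return(empty_cohort())
  with_seed(spec$seed, {
    cohort <- data.frame(
      case_id = sprintf("case_%06d", seq_len(n)),
      age = pmax(18, stats::rnorm(n, spec$age_mean, spec$age_sd)),
      sex = ifelse(stats::runif(n) < spec$female_frac, "female", "male"),
      ambulance = ifelse(stats::runif(n) < 0.358, "yes", "no"),
      referred = ifelse(stats::runif(n) < 0.239, "yes", "no"),
      injury_visit = ifelse(stats::runif(n) < 0.009, "yes", "no"),
      triage = sample(TRIAGE_LEVELS, n, replace = TRUE,
                      prob = c(0.051, 0.261, 0.584, 0.103, 0.001)),
      mental_status = sample(MENTAL_LEVELS, n, replace = TRUE,
                             prob = c(0.904, 0.070, 0.019, 0.007)),
      sbp = pmax(40, stats::rnorm(n, 136.1, 28.2)),
      dbp = pmax(20, stats::rnorm(n, 76.5, 15.1)),
      hr = pmax(20, stats::rnorm(n, 99.6, 20.1)),
      rr = pmax(5, stats::rnorm(n, 19.8, 4.4)),
      bt = pmax(33, stats::rnorm(n, 37.4, 1.1)),
      chills = ifelse(stats::runif(n) < 0.247, "yes", "no"),
      vomiting = ifelse(stats::runif(n) < 0.104, "yes", "no"),
      abdominal_pain = ifelse(stats::runif(n) < 0.171, "yes", "no"),
      stringsAsFactors = FALSE
    )
    cohort$site <- sample(SITE_LEVELS, n, replace = TRUE,
                          prob = spec$site_probs[SITE_LEVELS])
    cohort$note <- generate_notes(cohort$site, cohort$chills == "yes",
                                  spec$vocab)
    eta <- cohort_eta(cohort, spec)
    intercept <- spec$intercept %||% calibrate_intercept(
      eta, spec$target_prevalence)
    cohort$true_risk <- stats::plogis(intercept + eta)
    cohort$label <- as.integer(stats::runif(n) < cohort$true_risk)
    attr(cohort, "intercept") <- intercept
    if (spec$missing_rate > 0) {
      cohort <- inject_missingness(cohort, spec$missing_rate)
    }
    cohort
  })
}

# Root-find the intercept c so that mean(plogis(c + eta)) == target.
calibrate_intercept <- function(eta, target) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - target
  stats::uniroot(f, lower = -40, upper = 40, tol = 1e-12)$root
}

#' Generate one synthetic physician note
#'
#' Tokens are included independently with probabilities that depend on the
#' infection-site latent class and the chills symptom; punctuation and mixed
#' case are injected so downstream text preprocessing is exercised. The note
#' always contains at least one token.
#'
#' @param site One of `"respiratory"`, `"abdominal"`, `"other"`.
#' @param chills Logical; structured chills symptom present.
#' @param vocab Vocabulary data.frame, see [default_vocab()].
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return A single character string.
#' @export
generate_note <- function(site = "other", chills = FALSE,
                          vocab = default_vocab(), seed = NULL) {
  if (is.null(seed)) {
    generate_notes(site, chills, vocab)
  } else {
    with_seed(seed, generate_notes(site, chills, vocab))
  }
}

generate_notes <- function(site, chills, vocab) {
  if (NROW(vocab) == 0) stop("vocabulary must be nonempty")
  if (!all(site %in% SITE_LEVELS)) stop("unknown infection-site class")
  n <- max(length(site), length(chills))
  site <- rep_len(site, n); chills <- rep_len(chills, n)
  pm <- cbind(other = vocab$p_other, respiratory = vocab$p_resp,
              abdominal = vocab$p_abdo)
  vapply(seq_len(n), function(i) {
    p <- pmin(1, pm[, site[i]] + if (chills[i]) vocab$p_chills else 0)
    inc <- stats::runif(nrow(vocab)) < p
    toks <- vocab$token[inc]
    if (length(toks) == 0) toks <- vocab$token[sample.int(nrow(vocab), 1)]
    toks <- sample(toks)          # shuffle word order
    # inject punctuation / capitalization noise
    caps <- stats::runif(length(toks)) < 0.15
    toks[caps] <- toupper(toks[caps])
    substr(toks[1], 1, 1) <- toupper(substr(toks[1], 1, 1))
    punct <- ifelse(stats::runif(length(toks)) < 0.2, ",", "")
    out <- paste0(toks, punct, collapse = " ")
    paste0(out, ".")
  }, character(1))
}

#' Inject missingness into vital-sign columns
#'
#' Each eligible cell (SBP, DBP, HR, RR, BT) is set missing independently
#' with probability `rate`; all other columns, notes, and labels are
#' untouched.
#'
#' @param cohort Cohort data.frame.
#' @param rate Missingness probability in `[0, 1]`.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, rate, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) ||
      rate < 0 || rate > 1) {
    stop("`rate` must be a probability in [0, 1]")
  }
  if (rate == 0 || nrow(cohort) == 0) return(cohort)
  run <- function() {
    for (v in VITAL_VARS) {
      hit <- stats::runif(nrow(cohort)) < rate
      cohort[[v]][hit] <- NA_real_
    }
    cohort
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write / read a cohort as plain-text files
#'
#' The cohort table is written as UTF-8 CSV with a header row and empty
#' strings for missing values (notes excluded); notes go to JSONL, one
#' `{"case_id": ..., "note": ...}` object per line.
#'
#' @param cohort Cohort data.frame.
#' @param csv_path Path for the structured CSV.
#' @param notes_path Optional path for the notes JSONL.
#' @return `write_cohort` returns the paths invisibly; `read_cohort` returns
#'   the cohort data.frame.
#' @export
write_cohort <- function(cohort, csv_path, notes_path = NULL) {
  tab <- cohort[, setdiff(names(cohort), "note"), drop = FALSE]
  utils::write.csv(tab, csv_path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  if (!is.null(notes_path)) {
    lines <- vapply(seq_len(nrow(cohort)), function(i) {
      jsonlite::toJSON(list(case_id = cohort$case_id[i],
                            note = cohort$note[i]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, notes_path, useBytes = TRUE)
  }
  invisible(c(csv_path, notes_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(csv_path, notes_path = NULL) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         na.strings = "", fileEncoding = "UTF-8")
  if (!is.null(notes_path)) {
    recs <- lapply(readLines(notes_path, encoding = "UTF-8"),
                   jsonlite::fromJSON)
    notes <- stats::setNames(vapply(recs, `[[`, character(1), "note"),
                             vapply(recs, `[[`, character(1), "case_id"))
    tab$note <- unname(notes[tab$case_id])
  }
  tab
}
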