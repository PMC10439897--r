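# Preprocessing: standardized/one-hot structured features and TF-IDF note
# vectors. All statistics are fitted on training data only; fitted objects
# are plain immutable lists.

#' Structured-variable schema
#'
#' Fixed ordering of the six continuous variables and nine categorical
#' variables with closed level sets, so feature indices are stable across
#' fits. Unknown categorical levels are an error at transform time.
#'
#' @return A list with `continuous` (character vector) and `categorical`
#'   (named list of level vectors), class `structured_schema`.
#' @export
structured_schema <- function() {
  structure(list(
    continuous = c("age", "sbp", "dbp", "hr", "rr", "bt"),
    categorical = list(
      sex = SEX_LEVELS,
      ambulance = YESNO_LEVELS,
      referred = YESNO_LEVELS,
      injury_visit = YESNO_LEVELS,
      triage = as.character(TRIAGE_LEVELS),
      mental_status = MENTAL_LEVELS,
      chills = YESNO_LEVELS,
      vomiting = YESNO_LEVELS,
      abdominal_pain = YESNO_LEVELS
    )
  ), class = "structured_schema")
}

#' Fit imputation means and standardization for continuous variables
#'
#' Means and SDs are computed on observed (non-missing) training values only.
#' Missing values are permitted in vital signs; a variable with no observed
#' values is an error. A constant column gets scale 1 (flagged in
#' `$constant`), so its standardized values are all zero.
#'
#' @param cases Training cohort data.frame.
#' @param schema A [structured_schema()].
#' @return A `fitted_scaler`: per-variable `mean` (also the imputation value)
#'   and `scale`.
#' @export
fit_structured <- function(cases, schema = structured_schema()) {
  stopifnot(nrow(cases) >= 2)
  vars <- schema$continuous
  mu <- sc <- stats::setNames(numeric(length(vars)), vars)
  constant <- stats::setNames(logical(length(vars)), vars)
  for (v in vars) {
    x <- cases[[v]]
    x <- x[!is.na(x)]
    if (length(x) == 0) stop(sprintf("variable '%s' has no observed values", v))
    mu[v] <- mean(x)
    s <- sqrt(mean((x - mu[v])^2))   # population SD (unit-variance scaling)
    if (!is.finite(s) || s == 0) {
      sc[v] <- 1
      constant[v] <- TRUE
    } else {
      sc[v] <- s
    }
  }
  structure(list(mean = mu, scale = sc, constant = constant),
            class = "fitted_scaler")
}

#' Transform cases to the standardized + one-hot feature matrix
#'
#' Missing vitals are imputed with the training means before centring, so an
#' imputed cell maps to exactly 0. Categorical variables are expanded to full
#' one-hot blocks (no reference level dropped); an unknown level is an error
#' naming the variable and level. Column count is
#' `length(continuous) + sum(level counts)`.
#'
#' @param cases Cohort data.frame.
#' @param scaler A fitted [fit_structured()] scaler.
#' @param schema A [structured_schema()].
#' @return Numeric matrix, one row per case, with named columns.
#' @export
transform_structured <- function(cases, scaler, schema = structured_schema()) {
  stopifnot(inherits(scaler, "fitted_scaler"))
  n <- nrow(cases)
  blocks <- list()
  for (v in schema$continuous) {
    x <- cases[[v]]
    x[is.na(x)] <- scaler$mean[v]
    blocks[[v]] <- matrix((x - scaler$mean[v]) / scaler$scale[v],
                          ncol = 1, dimnames = list(NULL, v))
  }
  for (v in names(schema$categorical)) {
    levs <- schema$categorical[[v]]
    x <- as.character(cases[[v]])
    bad <- !(x %in% levs)
    if (any(bad)) {
      stop(sprintf("unknown level '%s' for variable '%s'",
                   x[which(bad)[1]], v))
    }
    m <- matrix(0, nrow = n, ncol = length(levs),
                dimnames = list(NULL, paste(v, levs, sep = "=")))
    m[cbind(seq_len(n), match(x, levs))] <- 1
    blocks[[v]] <- m
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

# Column-index groups (one per structured variable) of the one-hot matrix;
# used to group attributions in feature-importance reporting.
structured_feature_groups <- function(schema = structured_schema()) {
  groups <- list()
  idx <- 0
  for (v in schema$continuous) {
    groups[[v]] <- idx + 1L
    idx <- idx + 1L
  }
  for (v in names(schema$categorical)) {
    k <- length(schema$categorical[[v]])
    groups[[v]] <- idx + seq_len(k)
    idx <- idx + k
  }
  groups
}

#' Tokenize a free-text note
#'
#' Lowercases, splits on any non-alphanumeric character (Unicode-aware),
#' removes stopwords, and applies a pluggable token-wise lemmatizer (default
#' identity). Token order is preserved. Language-specific stopword lists and
#' lemmatizers are injected by the caller.
#'
#' @param text Character vector of notes.
#' @param stopwords Character vector of tokens to drop.
#' @param lemmatizer Function token vector -> token vector (element-wise).
#' @return For a single note, a character vector of tokens; for multiple
#'   notes, a list of such vectors. Empty text yields an empty vector.
#' @export
tokenize_note <- function(text, stopwords = character(),
                          lemmatizer = identity) {
  one <- function(txt) {
    if (is.na(txt) || !nzchar(txt)) return(character())
    toks <- strsplit(tolower(txt), "[^[:alnum:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    toks <- toks[!(toks %in% stopwords)]
    if (length(toks)) toks <- as.character(lemmatizer(toks))
    toks
  }
  if (length(text) == 1) one(text) else lapply(text, one)
}

#' Fit a TF-IDF model on tokenized training documents
#'
#' Vocabulary keeps tokens whose document frequency satisfies
#' `df / N >= min_df` (ties kept), sorted lexicographically. IDF uses the
#' smoothed form `idf(t) = ln((1 + N) / (1 + df(t))) + 1`.
#'
#' @param docs List of token vectors (one per training document).
#' @param min_df Minimum document-frequency proportion (default 0.01).
#' @return A `tfidf_model`: `vocabulary`, `df`, `idf`, `min_df`, `n_docs`.
#' @export
fit_tfidf <- function(docs, min_df = 0.01) {
  if (length(docs) == 0) stop("empty corpus")
  n <- length(docs)
  df_tab <- table(unlist(lapply(docs, unique)))
  keep <- as.numeric(df_tab) / n >= min_df
  vocab <- sort(names(df_tab)[keep], method = "radix")
  df <- as.numeric(df_tab[vocab])
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(vocabulary = vocab,
                 df = stats::setNames(df, vocab),
                 idf = stats::setNames(idf, vocab),
                 min_df = min_df, n_docs = n),
            class = "tfidf_model")
}

#' Transform tokenized documents to L2-normalized TF-IDF vectors
#'
#' Entry for token t is `count(t) * idf(t)`, then each document vector is
#' L2-normalized (an all-out-of-vocabulary document stays the zero vector).
#' Out-of-vocabulary tokens are ignored silently.
#'
#' @param docs A token vector or list of token vectors.
#' @param model A fitted [fit_tfidf()] model.
#' @return Numeric matrix, one row per document, one column per vocabulary
#'   token.
#' @export
transform_tfidf <- function(docs, model) {
  stopifnot(inherits(model, "tfidf_model"))
  if (!is.list(docs)) docs <- list(docs)
  vocab <- model$vocabulary
  out <- matrix(0, nrow = length(docs), ncol = length(vocab),
                dimnames = list(NULL, vocab))
  for (i in seq_along(docs)) {
    toks <- docs[[i]][docs[[i]] %in% vocab]
    if (length(toks) == 0) next
    tf <- table(toks)
    v <- as.numeric(tf) * model$idf[names(tf)]
    nrm <- sqrt(sum(v^2))
    out[i, names(tf)] <- v / nrm
  }
  out
}
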