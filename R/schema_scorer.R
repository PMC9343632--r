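#' Map a continuous activation to the ordinal 0--3 presence scale
#'
#' The scorer emits activations in [0, 1]; human-readable labels use an
#' ordinal scale from 0 (schema not present) to 3 (schema clearly present).
#' The map is a monotone step function over configurable bin edges; bins
#' are half-open on the right, `[0, t1) [t1, t2) [t2, t3) [t3, 1]`, with
#' equal-width edges by default. Vectorised.
#'
#' @param activation Numeric value(s) in [0, 1].
#' @param thresholds Strictly increasing bin edges in (0, 1), length 3.
#' @return Integer code(s) in {0, 1, 2, 3}.
#' @export
activation_to_ordinal <- function(activation, thresholds = c(0.25, 0.5, 0.75)) {
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0) ||
      any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must be 3 strictly increasing values in (0, 1)")
  }
  if (any(is.na(activation)) || any(activation < 0 | activation > 1)) {
    stop("activations must lie in [0, 1]")
  }
  codes <- findInterval(activation, thresholds)  # half-open on the right
  as.integer(codes)
}

# ---- scorer interface ------------------------------------------------------

new_schema_scorer <- function(score_fn, name, schemas, provenance = "unknown",
                              thresholds = c(0.25, 0.5, 0.75), model = NULL) {
  structure(list(score_fn = score_fn, name = name, schemas = schemas,
                 provenance = provenance, thresholds = thresholds,
                 model = model),
            class = "schema_scorer")
}

#' @export
print.schema_scorer <- function(x, ...) {
  cat(sprintf("<schema_scorer '%s'> (%s)\n", x$name, x$provenance))
  invisible(x)
}

#' Score one utterance against the nine schemas
#'
#' @param scorer A `schema_scorer` (see [train_baseline_scorer()] or
#'   [lexicon_scorer()]).
#' @param text Non-empty utterance text.
#' @param utterance_id Identifier attached to the result.
#' @return A [schema_activation()] with activations and ordinal codes.
#' @export
score_utterance <- function(scorer, text, utterance_id = "u1") {
  stopifnot(inherits(scorer, "schema_scorer"))
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("text must be a single non-empty string")
  }
  a <- scorer$score_fn(text)
  check_schema_vector(a, "scorer output")
  if (any(a < 0 | a > 1)) stop("scorer returned activations outside [0, 1]")
  schema_activation(utterance_id, a, thresholds = scorer$thresholds)
}

#' Aggregate schema activations over a whole thought record
#'
#' The utterances eligible for schema scoring are the automatic thought and
#' every downward-arrow step (the situation/emotion/behavior fields are not
#' scored). The record-level activation of each schema is the element-wise
#' maximum over these utterances: any single thought revealing a schema is
#' enough to mark it active for the record.
#'
#' @param scorer A `schema_scorer`.
#' @param record A completed [thought_record()].
#' @return Numeric 9-vector of record-level activations in [0, 1].
#' @export
score_record <- function(scorer, record) {
  stopifnot(inherits(record, "thought_record"))
  texts <- c(record$automatic_thought, record$downward_steps)
  acts <- vapply(texts, function(t) {
    score_utterance(scorer, t)$activations
  }, numeric(9))
  apply(matrix(acts, nrow = 9L), 1L, max)
}

# ---- text utilities --------------------------------------------------------

tokenize <- function(text) {
  toks <- strsplit(tolower(gsub("[^a-z' ]", " ", tolower(text))), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Simple lexicon-based schema scorer
#'
#' A transparent, training-free scorer: each schema has a keyword lexicon
#' and the activation is `hits / (hits + 1)` where `hits` is the number of
#' lexicon tokens present in the utterance. Useful as a deterministic
#' default for end-to-end runs of the dialogue engine; for data-driven
#' scoring use [train_baseline_scorer()].
#'
#' @param schemas A [schema_set()].
#' @param lexicon Named list (one entry per schema, in schema order) of
#'   character keyword vectors; defaults to a built-in lexicon aligned with
#'   the synthetic-participant vocabulary.
#' @return A `schema_scorer`.
#' @export
lexicon_scorer <- function(schemas = default_schema_set(),
                           lexicon = default_schema_lexicon()) {
  if (length(lexicon) != 9L) stop("lexicon must have one entry per schema")
  lexicon <- lapply(lexicon, tolower)
  score_fn <- function(text) {
    toks <- unique(tokenize(text))
    hits <- vapply(lexicon, function(words) sum(toks %in% words), numeric(1))
    hits / (hits + 1)
  }
  new_schema_scorer(score_fn, "lexicon", schemas,
                    provenance = "built-in keyword lexicon")
}

#' Built-in keyword lexicon for the nine default schemas
#' @return Named list of 9 keyword vectors.
#' @export
default_schema_lexicon <- function() {
  list(
    `Attachment` = c("alone", "lonely", "abandoned", "unloved", "unlovable",
                     "rejected", "left", "unwanted"),
    `Competence` = c("failure", "fail", "incompetent", "useless", "inadequate",
                     "stupid", "capable", "succeed"),
    `Global self-evaluation` = c("worthless", "bad", "terrible", "awful",
                                 "person", "broken", "flawed"),
    `Health` = c("sick", "ill", "illness", "disease", "dying", "unhealthy",
                 "body", "pain"),
    `Power and control` = c("helpless", "powerless", "trapped", "control",
                            "stuck", "weak"),
    `Meta-cognition` = c("overthinking", "thoughts", "mind", "crazy",
                         "irrational", "cope", "coping"),
    `Others' views on self` = c("judge", "judged", "laughing", "embarrassing",
                                "think", "opinion", "ridiculous"),
    `Hopelessness` = c("hopeless", "pointless", "future", "never", "nothing",
                       "improve", "better"),
    `Other people's wellbeing` = c("burden", "hurt", "disappoint",
                                   "disappointing", "upset", "harm", "worry")
  )
}

# ---- trainable bag-of-words baseline --------------------------------------

# internal ridge-penalised logistic regression (IRLS); intercept unpenalised
ridge_logistic <- function(X, y, lambda = 1, max_iter = 50L, tol = 1e-8) {
  p <- ncol(X)
  Xd <- cbind(1, X)
  beta <- numeric(p + 1L)
  pen <- c(0, rep(lambda, p))
  for (i in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xd, Xd * w) + diag(pen, p + 1L)
    beta_new <- solve(H, crossprod(Xd, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' Train the bag-of-words baseline schema scorer
#'
#' A transparent stand-in for the neural utterance classifiers used in the
#' original deployment: nine one-vs-rest ridge-penalised logistic
#' regressions on binary bag-of-words features. The positive class of
#' schema s is "ordinal code > 0" (schema at least a little bit present).
#' Training is deterministic given the corpus; no random initialisation is
#' used, so a seed is not required.
#'
#' @param corpus A labelled corpus: list with `texts` (character vector) and
#'   `ordinal` (utterance x 9 integer matrix of codes in {0,1,2,3}), as
#'   produced by [generate_labelled_corpus()].
#' @param schemas A [schema_set()].
#' @param lambda Ridge penalty on word weights (intercept unpenalised).
#' @param min_positive Minimum positive utterances required per schema.
#' @param thresholds Ordinal bin edges passed to the scorer.
#' @return A `schema_scorer`.
#' @export
train_baseline_scorer <- function(corpus, schemas = default_schema_set(),
                                  lambda = 1, min_positive = 10L,
                                  thresholds = c(0.25, 0.5, 0.75)) {
  stopifnot(is.list(corpus), !is.null(corpus$texts), !is.null(corpus$ordinal))
  texts <- corpus$texts
  ordinal <- corpus$ordinal
  if (length(texts) != nrow(ordinal)) stop("texts and labels differ in length")
  y_bin <- ordinal != 0L
  n_pos <- colSums(y_bin)
  if (any(n_pos < min_positive)) {
    bad <- schemas$names[n_pos < min_positive]
    stop("too few positive utterances (< ", min_positive, ") for schema(s): ",
         paste(bad, collapse = ", "))
  }
  token_lists <- lapply(texts, function(t) unique(tokenize(t)))
  vocab <- sort(unique(unlist(token_lists)))
  X <- matrix(0, length(texts), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(token_lists)) X[i, token_lists[[i]]] <- 1
  coefs <- vapply(seq_len(9L), function(s) {
    ridge_logistic(X, as.numeric(y_bin[, s]), lambda = lambda)
  }, numeric(length(vocab) + 1L))
  model <- list(vocab = vocab, coefs = coefs, lambda = lambda)
  score_fn <- function(text) {
    toks <- unique(tokenize(text))
    x <- as.numeric(model$vocab %in% toks)
    if (!any(x > 0)) return(numeric(9L))  # no vocabulary overlap: floor at 0
    stats::plogis(drop(crossprod(model$coefs, c(1, x))))
  }
  new_schema_scorer(score_fn, "bag-of-words baseline", schemas,
                    provenance = sprintf(
                      "trained on %d utterances, vocab %d, ridge lambda %g",
                      length(texts), length(vocab), lambda),
                    thresholds = thresholds, model = model)
}

#' Serialize / load a trained baseline scorer
#'
#' The model (vocabulary, coefficient matrix, schema set, thresholds) is
#' written as a single JSON file. Loading refuses to score if the embedded
#' schema set does not match the one supplied.
#'
#' @param scorer A trained `schema_scorer` (must carry a model).
#' @param path JSON file path.
#' @param schemas Expected [schema_set()] when reading.
#' @return `path` invisibly (write); a `schema_scorer` (read).
#' @export
write_scorer <- function(scorer, path) {
  stopifnot(inherits(scorer, "schema_scorer"))
  if (is.null(scorer$model)) stop("only trained scorers can be serialized")
  payload <- list(name = scorer$name, provenance = scorer$provenance,
                  schema_names = scorer$schemas$names,
                  thresholds = scorer$thresholds,
                  vocab = scorer$model$vocab,
                  lambda = scorer$model$lambda,
                  coefs = scorer$model$coefs)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path, schemas = default_schema_set()) {
  payload <- jsonlite::fromJSON(path)
  if (!identical(as.character(payload$schema_names), schemas$names)) {
    stop("scorer schema set does not match the supplied schema_set; ",
         "refusing to score")
  }
  model <- list(vocab = payload$vocab,
                coefs = matrix(unlist(payload$coefs),
                               nrow = length(payload$vocab) + 1L),
                lambda = payload$lambda)
  score_fn <- function(text) {
    toks <- unique(tokenize(text))
    x <- as.numeric(model$vocab %in% toks)
    if (!any(x > 0)) return(numeric(9L))
    stats::plogis(drop(crossprod(model$coefs, c(1, x))))
  }
  new_schema_scorer(score_fn, payload$name, schemas,
                    provenance = payload$provenance,
                    thresholds = payload$thresholds, model = model)
}
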