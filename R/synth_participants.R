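#' Configure a synthetic chat persona
#'
#' Personas drive scripted sessions through the dialogue engine: a mixture
#' profile over the nine schemas governs which vocabulary their thoughts
#' use, `chain_depth_distribution` governs how many downward-arrow steps
#' they produce, and `stop_behavior` is the per-turn probability of
#' stopping the arrow early.
#'
#' @param schema_profile Non-negative 9-vector of mixture weights
#'   (normalised to sum 1).
#' @param verbosity Mean number of filler words per utterance.
#' @param chain_depth_distribution Function `(k) -> k` depth draws, or a
#'   single number for a geometric distribution with that mean.
#' @param stop_behavior Probability in [0, 1] of stopping the downward
#'   arrow at each turn (applied on top of the depth draw; 1 means zero
#'   steps always).
#' @return An object of class `persona_config`.
#' @export
persona_config <- function(schema_profile = rep(1 / 9, 9), verbosity = 6,
                           chain_depth_distribution = 3,
                           stop_behavior = 0) {
  check_schema_vector(schema_profile, "schema_profile")
  if (any(schema_profile < 0) || sum(schema_profile) <= 0) {
    stop("schema_profile weights must be non-negative and not all zero")
  }
  if (stop_behavior < 0 || stop_behavior > 1) {
    stop("stop_behavior must be a probability")
  }
  depth_fn <- if (is.function(chain_depth_distribution)) {
    chain_depth_distribution
  } else {
    mean_depth <- chain_depth_distribution
    if (mean_depth < 0) stop("mean chain depth must be non-negative")
    # geometric on {0, 1, ...} with the requested mean
    function(k) stats::rgeom(k, prob = 1 / (1 + mean_depth))
  }
  structure(list(schema_profile = schema_profile / sum(schema_profile),
                 verbosity = verbosity, depth_fn = depth_fn,
                 stop_behavior = stop_behavior),
            class = "persona_config")
}

# schema-specific utterance templates; strength 1..3 controls how many
# signature keywords appear, which fixes the ordinal code by construction
schema_templates <- function() {
  lex <- default_schema_lexicon()
  filler <- c("i", "feel", "that", "really", "it", "seems", "like", "am",
              "so", "very", "today", "again", "always", "maybe", "somehow")
  list(lexicon = lex, filler = filler)
}

make_utterance <- function(schema_idx, strength, verbosity) {
  tpl <- schema_templates()
  words <- tpl$lexicon[[schema_idx]]
  n_key <- min(strength, length(words))
  keys <- sample(words, n_key)
  n_fill <- max(1L, stats::rpois(1L, verbosity))
  fills <- sample(tpl$filler, n_fill, replace = TRUE)
  paste(sample(c(keys, fills)), collapse = " ")
}

#' Generate an input script that drives a session to completion
#'
#' Produces the ordered user turns (button tokens and free text) that take
#' a fresh [start_session()] state all the way to the closing phase.
#' Session 1 scripts complete the two mandatory scenario records; session 2
#' scripts complete `n_records` personal records then decline to continue.
#'
#' @param persona A [persona_config()].
#' @param session_index 1 or 2.
#' @param n_records Number of personal records in session 2 (>= 1).
#' @param stop_token Downward-arrow stop token (must match the engine
#'   config).
#' @param seed Optional seed.
#' @return Character vector of user inputs.
#' @export
generate_transcript_script <- function(persona, session_index = 1L,
                                       n_records = 1L, stop_token = "done",
                                       seed = NULL) {
  stopifnot(inherits(persona, "persona_config"))
  if (!is.null(seed)) set.seed(seed)
  session_index <- as.integer(session_index)
  n_rec <- if (session_index == 1L) 2L else max(1L, as.integer(n_records))
  draw_schema <- function() {
    sample.int(9L, 1L, prob = persona$schema_profile)
  }
  one_record <- function(is_last) {
    s <- draw_schema()
    depth <- persona$depth_fn(1L)
    if (persona$stop_behavior >= 1) depth <- 0L
    steps <- character()
    for (k in seq_len(depth)) {
      if (persona$stop_behavior > 0 &&
          stats::runif(1) < persona$stop_behavior) break
      steps <- c(steps, make_utterance(s, sample(1:3, 1L),
                                       persona$verbosity))
    }
    fields <- c(
      make_utterance(s, 1L, persona$verbosity),               # situation
      sample(c("sad", "anxious", "ashamed", "frustrated", "hurt"), 1L),
      make_utterance(s, sample(2:3, 1L), persona$verbosity),  # thought
      sample(c("i went home", "i said nothing", "i avoided everyone",
               "i kept working", "i cried"), 1L)
    )
    turns <- c(fields, steps, stop_token, "ok")
    if (session_index == 1L) {
      c("ready", turns, if (!is_last) "yes")
    } else {
      c(turns, if (is_last) "no" else "yes")
    }
  }
  unlist(lapply(seq_len(n_rec), function(i) one_record(i == n_rec)))
}

#' Generate a labelled utterance corpus
#'
#' Assembles utterances from schema-specific keyword templates. Each
#' utterance carries one generating schema; the template strength (number
#' of signature keywords: 1, 2 or 3) directly sets the ordinal code for
#' that schema, all other schemas are coded 0. The generating schema is
#' drawn from the mixture of the supplied personas.
#'
#' @param personas List of [persona_config()]s (or a single one).
#' @param n_utterances Number of utterances to generate.
#' @param seed Optional seed.
#' @return A labelled corpus: list with `texts`, `ordinal` (n x 9 integer
#'   matrix) and `schema_idx` (generating schema per utterance).
#' @export
generate_labelled_corpus <- function(personas, n_utterances, seed = NULL) {
  if (inherits(personas, "persona_config")) personas <- list(personas)
  if (!length(personas)) stop("at least one persona is required")
  stopifnot(all(vapply(personas, inherits, TRUE, "persona_config")))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_utterances)
  texts <- character(n)
  ordinal <- matrix(0L, n, 9L)
  schema_idx <- integer(n)
  for (i in seq_len(n)) {
    p <- personas[[((i - 1L) %% length(personas)) + 1L]]
    s <- sample.int(9L, 1L, prob = p$schema_profile)
    strength <- sample(1:3, 1L)
    texts[i] <- make_utterance(s, strength, p$verbosity)
    ordinal[i, s] <- strength
    schema_idx[i] <- s
  }
  list(texts = texts, ordinal = ordinal, schema_idx = schema_idx)
}

#' Generate Likert responses with a target reliability
#'
#' One-factor model: item j of participant i is a common factor plus
#' unique noise, discretized to the response range. The inter-item
#' correlation implied by the target alpha (via the Spearman-Brown
#' identity `alpha = k r / (1 + (k-1) r)`) is inflated beforehand to
#' compensate for the attenuation caused by discretizing to a small number
#' of response categories, so the realized alpha of the discrete data
#' matches the target.
#'
#' @param n Participants (>= 2).
#' @param n_items Items.
#' @param response_range Integer `(min, max)` response scale.
#' @param target_alpha Target Cronbach alpha in [0, 1).
#' @param seed Optional seed.
#' @param subscale Subscale identity stamped on the result.
#' @return A [likert_matrix()].
#' @export
generate_likert <- function(n, n_items = 6L, response_range = c(1L, 6L),
                            target_alpha = 0.85, seed = NULL,
                            subscale = "engagement") {
  if (n < 2L) stop("n must be at least 2 for a reliability target")
  if (target_alpha < 0 || target_alpha >= 1) {
    stop("target_alpha must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(n_items)
  r_bar <- if (target_alpha == 0) 0 else
    target_alpha / (k - (k - 1) * target_alpha)
  if (r_bar >= 1) stop("target alpha infeasible for this item count")
  n_cat <- response_range[2] - response_range[1] + 1L
  # attenuation of a standard-normal item when rounded to n_cat categories;
  # corr(continuous, discretized) computed from the category midpoint map
  atten <- discretization_correlation(n_cat)
  r_lat <- min(r_bar / atten^2, 0.999)
  loading <- sqrt(r_lat)
  f <- stats::rnorm(n)
  resp <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    x <- loading * f + sqrt(1 - r_lat) * stats::rnorm(n)
    resp[, j] <- discretize_normal(x, response_range)
  }
  likert_matrix(resp, subscale = subscale, response_range = response_range)
}

# map a standard normal to equal-width categories over +/- 2.5 sd
discretize_normal <- function(x, response_range) {
  n_cat <- response_range[2] - response_range[1] + 1L
  edges <- seq(-2.5, 2.5, length.out = n_cat + 1L)[2:n_cat]
  response_range[1] + findInterval(x, edges)
}

discretization_correlation <- function(n_cat) {
  # corr between N(0,1) and its discretized version, by quadrature
  x <- seq(-6, 6, length.out = 4001L)
  w <- stats::dnorm(x)
  w <- w / sum(w)
  d <- discretize_normal(x, c(1L, n_cat))
  dm <- sum(w * d)
  xv <- sum(w * x^2) - sum(w * x)^2
  dv <- sum(w * d^2) - dm^2
  (sum(w * x * d) - sum(w * x) * dm) / sqrt(xv * dv)
}

#' Configure the synthetic study-table generator
#'
#' Structural equations emulating the trial dataset: NSR is a Likert sum
#' with target reliability; condition is assigned by minimization from NSR
#' buckets; insight is linear in condition (a-path); engagement is linear
#' in insight and the condition-by-NSR moderation, clipped to its 6--36
#' scale (producing the ceiling skew); the count outcome is a 1-truncated
#' Poisson whose log rate is linear in insight and condition.
#'
#' @param n Participants.
#' @param a_path Numeric 3-vector of condition effects on insight
#'   (low/medium/high), in insight scale points.
#' @param b_count Log-rate change of the count per insight point.
#' @param b_engagement Engagement points per insight point (raw scale).
#' @param direct_count Log-rate condition effects (3-vector).
#' @param direct_engagement Engagement condition effects (3-vector).
#' @param moderation_count,moderation_engagement Interaction coefficients
#'   (per centred-NSR point, for medium and high vs low), 2-vectors.
#' @param count_base_rate Baseline Poisson rate before truncation.
#' @param insight_mean,insight_sd Marginal insight distribution.
#' @param engagement_mean Engagement intercept (raw scale) -- near the
#'   ceiling by default to reproduce the negative skew.
#' @param engagement_sd Engagement residual SD.
#' @param nsr_items,nsr_alpha NSR subscale item count and reliability.
#' @param seed Integer seed.
#' @return An object of class `study_gen_config`.
#' @export
study_gen_config <- function(n = 306L, a_path = c(0, 0, 0), b_count = 0.03,
                             b_engagement = 0.4,
                             direct_count = c(0, 0, 0),
                             direct_engagement = c(0, 0, 0),
                             moderation_count = c(0, 0),
                             moderation_engagement = c(0, 0),
                             count_base_rate = 1.06,
                             insight_mean = 26, insight_sd = 4,
                             engagement_mean = 29.5, engagement_sd = 4,
                             nsr_items = 6L, nsr_alpha = 0.85, seed = 1L) {
  stopifnot(length(a_path) == 3L, length(direct_count) == 3L,
            length(direct_engagement) == 3L,
            length(moderation_count) == 2L,
            length(moderation_engagement) == 2L)
  if (insight_sd <= 0 || engagement_sd <= 0 || count_base_rate <= 0) {
    stop("scales and rates must be positive")
  }
  structure(as.list(environment()), class = "study_gen_config")
}

# draw from a 1-truncated Poisson by inverse cdf on the truncated support
rpois_1trunc <- function(n, lambda) {
  u <- stats::runif(n)
  p0 <- exp(-lambda)
  stats::qpois(p0 + u * (1 - p0), lambda)
}

#' Generate a full synthetic study table
#'
#' Conditions are assigned through the minimization randomizer from NSR
#' buckets (tertiles of the generated NSR scores), then mediator and
#' outcomes follow the configured structural equations. Counts are
#' 1-truncated (the second session mandated at least one record), so the
#' table satisfies the study-table invariants by construction.
#'
#' @param config A [study_gen_config()].
#' @return A validated study table (data.frame), with the NSR bucket in
#'   column `nsr_bucket`.
#' @export
generate_study_table <- function(config = study_gen_config()) {
  stopifnot(inherits(config, "study_gen_config"))
  set.seed(config$seed)
  n <- config$n
  nsr_m <- generate_likert(n, config$nsr_items, c(1L, 6L),
                           config$nsr_alpha,
                           subscale = "need_for_self_reflection")
  nsr <- score_subscale(nsr_m)
  bucket <- bucket_nsr(nsr, reference = nsr)
  alloc <- assign_stream(as.character(bucket),
                         allocation_state(seed = config$seed + 1L))
  condition <- factor(alloc$arms, levels = c("low", "medium", "high"))
  ci <- as.integer(condition)
  insight <- config$insight_mean + config$a_path[ci] +
    stats::rnorm(n, sd = config$insight_sd)
  insight_c <- insight - config$insight_mean
  nsr_c <- nsr - mean(nsr)
  mod_terms <- function(coefs) {
    ifelse(ci == 2L, coefs[1], ifelse(ci == 3L, coefs[2], 0)) * nsr_c
  }
  eng_latent <- config$engagement_mean + config$direct_engagement[ci] +
    config$b_engagement * insight_c + mod_terms(config$moderation_engagement) +
    stats::rnorm(n, sd = config$engagement_sd)
  engagement <- pmin(pmax(round(eng_latent), 6L), 36L)
  log_rate <- log(config$count_base_rate) + config$direct_count[ci] +
    config$b_count * insight_c + mod_terms(config$moderation_count)
  counts <- rpois_1trunc(n, exp(pmin(log_rate, 30)))
  table <- data.frame(
    participant_id = sprintf("synth%04d", seq_len(n)),
    condition = condition, nsr = nsr, nsr_bucket = bucket,
    insight = insight, engagement = engagement,
    n_voluntary_records = counts, stringsAsFactors = FALSE)
  validate_study_table(table)
}

#' Write / read a study table as CSV
#'
#' @param table A study table.
#' @param path CSV path.
#' @return `path` invisibly (write); a validated study table (read).
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(validate_study_table(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  validate_study_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
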