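#' PHQ-9 subclinical eligibility window
#'
#' Participants are screened on the 9-item patient health questionnaire
#' (total score 0--27); the subclinical window is the open interval
#' 4 < score < 8, i.e. scores 5, 6 and 7 are eligible. Vectorised.
#'
#' @param score Integer PHQ-9 total score(s) in [0, 27].
#' @return Logical vector.
#' @export
phq9_eligible <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 27) ||
      any(score != floor(score))) {
    stop("PHQ-9 scores must be integers in [0, 27]")
  }
  score > 4 & score < 8
}

#' Bucket a need-for-self-reflection score
#'
#' Maps a need-for-self-reflection (NSR) subscale sum to one of three
#' buckets (low, medium, high) via two cut-points. Bins are half-open:
#' `score < c1` is low, `c1 <= score < c2` is medium, `score >= c2` is
#' high. Cut-points default to the tertiles of a supplied reference sample.
#'
#' @param score Numeric NSR score(s).
#' @param cutpoints Two strictly increasing cut-points, or `NULL` to derive
#'   them from `reference`.
#' @param reference Numeric reference sample used when `cutpoints` is
#'   `NULL` (tertiles).
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
bucket_nsr <- function(score, cutpoints = NULL, reference = NULL) {
  if (is.null(cutpoints)) {
    if (is.null(reference)) {
      stop("supply either explicit cutpoints or a reference sample")
    }
    cutpoints <- unname(stats::quantile(reference, c(1 / 3, 2 / 3)))
  }
  if (length(cutpoints) != 2L || diff(cutpoints) <= 0) {
    stop("cutpoints must be two strictly increasing values")
  }
  idx <- findInterval(score, cutpoints) + 1L
  factor(c("low", "medium", "high")[idx], levels = c("low", "medium", "high"))
}

#' Create an empty minimization allocation state
#'
#' Tracks a 3x3 table of assignment counts (arm x NSR bucket), the seed of
#' the tie-breaking RNG, and the assignment log.
#'
#' @param seed Integer seed for random tie-breaking.
#' @return An object of class `allocation_state`.
#' @export
allocation_state <- function(seed = 1L) {
  counts <- matrix(0L, 3L, 3L,
                   dimnames = list(arm = c("low", "medium", "high"),
                                   bucket = c("low", "medium", "high")))
  structure(list(counts = counts, seed = as.integer(seed),
                 n_assigned = 0L,
                 log = data.frame(bucket = character(), arm = character(),
                                  stringsAsFactors = FALSE)),
            class = "allocation_state")
}

#' Assign a participant to an arm by minimization
#'
#' Single-variate minimization: the participant joins the arm with the
#' smallest assignment count within their NSR bucket; ties are broken
#' uniformly at random (deterministically reproducible from the state's
#' seed and the assignment history). With `biased_coin < 1` the minimizing
#' arm is chosen with that probability and the remaining arms share the
#' rest equally.
#'
#' @param bucket `"low"`, `"medium"` or `"high"` NSR bucket.
#' @param state An `allocation_state`.
#' @param biased_coin Probability of taking the minimizing arm (default 1 =
#'   plain minimization).
#' @return List with elements `arm` and `state` (updated).
#' @export
assign_arm <- function(bucket, state, biased_coin = 1) {
  stopifnot(inherits(state, "allocation_state"))
  bucket <- match.arg(as.character(bucket), c("low", "medium", "high"))
  if (biased_coin <= 0 || biased_coin > 1) {
    stop("biased_coin must be in (0, 1]")
  }
  arm_idx <- choose_arm(state$counts[, bucket], state$seed,
                        state$n_assigned, biased_coin)
  arm <- rownames(state$counts)[arm_idx]
  state$counts[arm_idx, bucket] <- state$counts[arm_idx, bucket] + 1L
  state$n_assigned <- state$n_assigned + 1L
  state$log <- rbind(state$log,
                     data.frame(bucket = bucket, arm = arm,
                                stringsAsFactors = FALSE))
  list(arm = arm, state = state)
}

# pick an arm for one decision; tie-breaking draws come from a decision-
# indexed substream so allocation is reproducible under resumption without
# replaying the whole stream
choose_arm <- function(counts, seed, counter, biased_coin = 1) {
  rs <- local_rng_state(seed, counter)
  on.exit(restore_rng_state(rs))
  minimal <- which(counts == min(counts))
  if (stats::runif(1) <= biased_coin || length(minimal) == 3L) {
    if (length(minimal) == 1L) minimal else
      minimal[sample.int(length(minimal), 1L)]
  } else {
    others <- setdiff(seq_len(3L), minimal)
    others[sample.int(length(others), 1L)]
  }
}

# seed the global RNG for one decision, returning the previous state
local_rng_state <- function(seed, counter) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed((seed + 1000003L * (counter %% 2048L)) %% .Machine$integer.max)
  old
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Assign a whole stream of participants
#'
#' @param buckets Character vector of NSR buckets in arrival order.
#' @param state An `allocation_state` (fresh or resumed).
#' @param biased_coin See [assign_arm()].
#' @return List with `arms` (character vector) and the final `state`.
#' @export
assign_stream <- function(buckets, state = allocation_state(),
                          biased_coin = 1) {
  buckets <- as.character(buckets)
  if (any(!buckets %in% c("low", "medium", "high"))) {
    stop("buckets must be low/medium/high")
  }
  arms <- character(length(buckets))
  counts <- state$counts
  counter <- state$n_assigned
  for (i in seq_along(buckets)) {
    b <- buckets[i]
    idx <- choose_arm(counts[, b], state$seed, counter, biased_coin)
    counts[idx, b] <- counts[idx, b] + 1L
    counter <- counter + 1L
    arms[i] <- rownames(counts)[idx]
  }
  state$counts <- counts
  state$n_assigned <- counter
  state$log <- rbind(state$log,
                     data.frame(bucket = buckets, arm = arms,
                                stringsAsFactors = FALSE))
  list(arms = arms, state = state)
}

#' Persist / resume an allocation state as JSON
#'
#' @param state An `allocation_state`.
#' @param path JSON file.
#' @return `path` invisibly (write); an `allocation_state` (read).
#' @export
write_allocation_state <- function(state, path) {
  stopifnot(inherits(state, "allocation_state"))
  payload <- list(counts = state$counts, seed = state$seed,
                  n_assigned = state$n_assigned, log = state$log)
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' @rdname write_allocation_state
#' @export
read_allocation_state <- function(path) {
  payload <- jsonlite::fromJSON(path)
  counts <- matrix(as.integer(unlist(payload$counts)), 3L, 3L,
                   dimnames = list(arm = c("low", "medium", "high"),
                                   bucket = c("low", "medium", "high")))
  log <- as.data.frame(payload$log, stringsAsFactors = FALSE)
  if (!nrow(log)) {
    log <- data.frame(bucket = character(), arm = character(),
                      stringsAsFactors = FALSE)
  }
  if (sum(counts) != nrow(log)) {
    stop("corrupt allocation state: counts and log disagree")
  }
  structure(list(counts = counts, seed = as.integer(payload$seed),
                 n_assigned = as.integer(payload$n_assigned), log = log),
            class = "allocation_state")
}
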