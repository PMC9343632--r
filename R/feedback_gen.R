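#' Acknowledgment messages shown after every completed thought record
#'
#' The low-richness feedback: a thank-you for completing the record and a
#' reminder that completing more thought records can reveal patterns of
#' thinking. Both richer tiers start with these same two messages, so the
#' text of lower tiers is always a prefix of higher ones.
#'
#' @return Character vector of two messages.
#' @export
low_feedback <- function() {
  c("Thank you for completing this thought record.",
    paste("Completing more thought records may help you gain insight into",
          "your patterns of thinking."))
}

#' Default reference distribution of downward-arrow step counts
#'
#' The step-count chart relates a user's chain length to how many people
#' reached each depth in a previous study. The true historical histogram is
#' not published; this synthetic default has a right-skewed shape with most
#' people completing 2-6 steps. Override via the `reference` argument of
#' [build_step_chart()] / [compose_feedback()] or a YAML file read with
#' [read_reference_distribution()].
#'
#' @return Named integer vector: names are step counts, values person counts.
#' @export
default_reference_distribution <- function() {
  c(`0` = 4L, `1` = 10L, `2` = 18L, `3` = 24L, `4` = 20L, `5` = 14L,
    `6` = 8L, `7` = 5L, `8` = 3L, `9` = 2L, `10` = 2L)
}

#' Read a step-count reference distribution from YAML
#'
#' @param path YAML file mapping step count to person count.
#' @return Named integer vector.
#' @export
read_reference_distribution <- function(path) {
  x <- yaml::read_yaml(path)
  if (length(x) == 0L) stop("reference distribution file is empty")
  counts <- as.integer(unlist(x))
  names(counts) <- names(x)
  if (any(is.na(as.integer(names(counts)))) || any(counts < 0)) {
    stop("reference distribution must map step counts to non-negative counts")
  }
  counts
}

#' Build step-count chart data (medium-richness feedback)
#'
#' Collects the number of downward-arrow steps of every record completed so
#' far (the last element is the current record) and situates the current
#' count in a reference distribution from a previous study. The percentile
#' uses the strictly-fewer convention: the percentage of reference people
#' who completed fewer steps than the current record.
#'
#' @param history Non-empty list of completed [thought_record()]s in
#'   completion order; the last element is the current record.
#' @param reference Named vector mapping step count to person count.
#' @return An object of class `step_chart_data` with fields
#'   `per_record_steps`, `reference_distribution`, `current_percentile`.
#' @export
build_step_chart <- function(history, reference = default_reference_distribution()) {
  if (!length(history)) stop("step chart requires at least one record")
  if (!length(reference) || sum(reference) == 0) {
    stop("reference distribution must be non-empty")
  }
  steps <- vapply(history, function(r) length(r$downward_steps), integer(1))
  current <- steps[length(steps)]
  ref_steps <- as.integer(names(reference))
  below <- sum(reference[ref_steps < current])
  structure(list(
    per_record_steps = steps,
    reference_distribution = reference,
    current_percentile = 100 * below / sum(reference)
  ), class = "step_chart_data")
}

#' Build spider-chart data (high-richness feedback)
#'
#' The current record's nine schema activations (blue dots) together with
#' the aggregate over all previous records of the same participant (orange
#' dots). The aggregate is the element-wise mean of per-record activation
#' vectors and excludes the current record; it is absent for the first
#' record.
#'
#' @param current Numeric 9-vector for the current record.
#' @param previous List of numeric 9-vectors, one per previous record.
#' @param schemas A [schema_set()] fixing the axis order.
#' @return An object of class `spider_data` with fields `axes`, `current`,
#'   `aggregate` (or `NULL`), `n_previous`.
#' @export
build_spider <- function(current, previous = list(),
                         schemas = default_schema_set()) {
  check_schema_vector(current, "current")
  if (any(current < 0 | current > 1)) stop("activations must lie in [0, 1]")
  for (v in previous) {
    check_schema_vector(v, "previous record vector")
  }
  aggregate <- if (length(previous)) {
    colMeans(do.call(rbind, previous))
  } else NULL
  structure(list(axes = schemas$names, current = as.numeric(current),
                 aggregate = aggregate, n_previous = length(previous)),
            class = "spider_data")
}

#' Compose the condition-dependent feedback bundle
#'
#' Assembles the feedback shown after a completed thought record at the
#' session's richness level: low = acknowledgment text only; medium = low
#' plus the step-count chart; high = medium plus the schema spider chart
#' (with schema definitions available on request). Message lists are nested:
#' low is a prefix of medium, medium a prefix of high.
#'
#' @param condition `"low"`, `"medium"` or `"high"`.
#' @param history Non-empty list of completed records (last = current).
#' @param reference Step-count reference distribution (medium/high).
#' @param scorer A `schema_scorer` (required for high).
#' @param schemas A [schema_set()].
#' @return An object of class `feedback_bundle`.
#' @export
compose_feedback <- function(condition, history,
                             reference = default_reference_distribution(),
                             scorer = NULL, schemas = default_schema_set()) {
  condition <- match.arg(condition, c("low", "medium", "high"))
  if (!length(history)) stop("feedback requires at least one completed record")
  msgs <- low_feedback()
  step_chart <- NULL
  spider <- NULL
  definitions <- NULL
  if (condition %in% c("medium", "high")) {
    step_chart <- build_step_chart(history, reference)
    msgs <- c(msgs, sprintf(
      paste("You completed %d downward-arrow step%s in this thought record;",
            "%.0f%% of people in a previous study completed fewer steps."),
      step_chart$per_record_steps[length(step_chart$per_record_steps)],
      if (step_chart$per_record_steps[length(step_chart$per_record_steps)] == 1L)
        "" else "s",
      step_chart$current_percentile))
  }
  if (condition == "high") {
    if (is.null(scorer)) stop("high-richness feedback requires a scorer")
    vectors <- lapply(history, function(r) score_record(scorer, r))
    n <- length(vectors)
    spider <- build_spider(vectors[[n]], vectors[-n], schemas)
    top <- schemas$names[which.max(spider$current)]
    msgs <- c(msgs, sprintf(
      paste("Your thoughts in this record point most strongly to the '%s'",
            "schema; the spider chart shows all nine schemas, with your",
            "previous records in orange."), top))
    definitions <- schemas$definitions
  }
  structure(list(richness = condition, text_messages = msgs,
                 step_chart = step_chart, spider = spider,
                 schema_definitions = definitions),
            class = "feedback_bundle")
}

#' @export
print.feedback_bundle <- function(x, ...) {
  cat(sprintf("<feedback_bundle richness=%s>\n", x$richness))
  cat(paste0("  ", x$text_messages, collapse = "\n"), "\n")
  if (!is.null(x$step_chart)) {
    cat(sprintf("  step chart: steps so far [%s], percentile %.1f\n",
                paste(x$step_chart$per_record_steps, collapse = ", "),
                x$step_chart$current_percentile))
  }
  if (!is.null(x$spider)) {
    cat(sprintf("  spider: top schema '%s' (%d previous records)\n",
                x$spider$axes[which.max(x$spider$current)],
                x$spider$n_previous))
  }
  invisible(x)
}

#' Serialize a feedback bundle to JSON
#'
#' @param bundle A `feedback_bundle`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
feedback_to_json <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "feedback_bundle"))
  payload <- list(
    richness = bundle$richness,
    text_messages = bundle$text_messages,
    step_chart = if (!is.null(bundle$step_chart)) {
      list(per_record_steps = bundle$step_chart$per_record_steps,
           reference_distribution = as.list(bundle$step_chart$reference_distribution),
           current_percentile = bundle$step_chart$current_percentile)
    },
    spider = if (!is.null(bundle$spider)) {
      list(axes = bundle$spider$axes, current = bundle$spider$current,
           aggregate = bundle$spider$aggregate,
           n_previous = bundle$spider$n_previous)
    },
    schema_definitions = as.list(bundle$schema_definitions)
  )
  if (is.null(path)) {
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, null = "null")))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
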