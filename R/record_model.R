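#' Construct a thought record
#'
#' A thought record is the structured CBT worksheet at the centre of the
#' package: what happened (situation), how it felt (emotion), the automatic
#' thought, what the person did (behavior), plus the ordered chain of
#' downward-arrow steps elicited from the automatic thought.
#'
#' Session 1 records are always scenario-based practice records; session 2
#' records always describe personal situations, so `origin` is constrained
#' by `session_index`.
#'
#' @param record_id,participant_id Opaque identifiers.
#' @param session_index 1 (scenario session) or 2 (personal session).
#' @param origin `"scenario"` or `"personal"`.
#' @param scenario_id Scenario identifier; required iff `origin = "scenario"`.
#' @param situation,emotion,automatic_thought,behavior The four core fields;
#'   must be non-empty in a completed record.
#' @param downward_steps Character vector of downward-arrow steps in
#'   elicitation order (may be empty).
#' @param created_at Monotone integer event counter (a logical clock, so
#'   transcripts replay byte-identically); defaults to 0.
#' @return An object of class `thought_record`.
#' @export
thought_record <- function(record_id, participant_id, session_index, origin,
                           situation, emotion, automatic_thought, behavior,
                           downward_steps = character(), scenario_id = NULL,
                           created_at = 0L) {
  session_index <- as.integer(session_index)
  if (!session_index %in% c(1L, 2L)) stop("session_index must be 1 or 2")
  origin <- match.arg(origin, c("scenario", "personal"))
  if (session_index == 1L && origin != "scenario") {
    stop("session 1 records must have origin = 'scenario'")
  }
  if (session_index == 2L && origin != "personal") {
    stop("session 2 records must have origin = 'personal'")
  }
  if (origin == "scenario" && (is.null(scenario_id) || !nzchar(scenario_id))) {
    stop("scenario_id is required for scenario-based records")
  }
  core <- c(situation = situation, emotion = emotion,
            automatic_thought = automatic_thought, behavior = behavior)
  empty <- !nzchar(trimws(core))
  if (any(empty)) {
    stop("core fields must be non-empty in a completed record: ",
         paste(names(core)[empty], collapse = ", "))
  }
  structure(list(
    record_id = as.character(record_id),
    participant_id = as.character(participant_id),
    session_index = session_index,
    origin = origin,
    scenario_id = if (origin == "scenario") as.character(scenario_id) else NA_character_,
    situation = situation, emotion = emotion,
    automatic_thought = automatic_thought, behavior = behavior,
    downward_steps = as.character(downward_steps),
    created_at = as.integer(created_at)
  ), class = "thought_record")
}

#' @export
print.thought_record <- function(x, ...) {
  cat(sprintf("<thought_record %s> session %d (%s)\n", x$record_id,
              x$session_index, x$origin))
  cat("  situation: ", x$situation, "\n", sep = "")
  cat("  emotion:   ", x$emotion, "\n", sep = "")
  cat("  thought:   ", x$automatic_thought, "\n", sep = "")
  cat("  behavior:  ", x$behavior, "\n", sep = "")
  if (length(x$downward_steps)) {
    cat("  downward-arrow chain (", length(x$downward_steps), " steps):\n",
        sep = "")
    cat(paste0("    -> ", x$downward_steps, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Per-utterance schema activation
#'
#' Stores the continuous activations in [0, 1] of the nine schemas for one
#' scored utterance together with their ordinal codes on the 0--3 scale
#' (0 = schema not present, 3 = schema clearly present). The ordinal codes
#' must be consistent with the activations under the supplied threshold map.
#'
#' @param utterance_id Opaque identifier.
#' @param activations Numeric 9-vector in [0, 1].
#' @param ordinal_codes Optional integer 9-vector in {0, 1, 2, 3}; derived
#'   from `activations` via [activation_to_ordinal()] when omitted.
#' @param thresholds Ordinal bin edges, see [activation_to_ordinal()].
#' @return An object of class `schema_activation`.
#' @export
schema_activation <- function(utterance_id, activations, ordinal_codes = NULL,
                              thresholds = c(0.25, 0.5, 0.75)) {
  check_schema_vector(activations, "activations")
  if (any(activations < 0 | activations > 1)) {
    stop("activations must lie in [0, 1]")
  }
  derived <- activation_to_ordinal(activations, thresholds)
  if (is.null(ordinal_codes)) {
    ordinal_codes <- derived
  } else {
    ordinal_codes <- as.integer(ordinal_codes)
    check_schema_vector(ordinal_codes, "ordinal_codes")
    if (any(!ordinal_codes %in% 0:3)) stop("ordinal codes must be in {0,1,2,3}")
    if (!identical(ordinal_codes, derived)) {
      stop("ordinal_codes are inconsistent with activations under the ",
           "threshold map")
    }
  }
  structure(list(utterance_id = as.character(utterance_id),
                 activations = as.numeric(activations),
                 ordinal_codes = ordinal_codes,
                 thresholds = thresholds),
            class = "schema_activation")
}

#' Recode an ordinal schema label to a binomial one
#'
#' Collapses the 0--3 ordinal presence scale to presence/absence:
#' 0 (schema not present) stays 0, any positive code (schema at least a
#' little bit present) becomes 1. Vectorised.
#'
#' @param code Integer code(s) in {0, 1, 2, 3}.
#' @return Integer 0/1 of the same length.
#' @export
recode_ordinal_to_binomial <- function(code) {
  if (length(code) == 0L) return(integer())
  if (any(is.na(code)) || any(!code %in% 0:3)) {
    stop("ordinal codes must be integers in {0, 1, 2, 3}")
  }
  as.integer(code != 0L)
}

#' Relative frequency distribution over the nine schemas
#'
#' For each schema, the fraction of utterances whose binomial recode of the
#' ordinal label is 1 (schema at least a little bit present). Frequencies
#' are computed over utterances, not records; a record-level view is
#' available through [score_record()] aggregation in the feedback layer.
#'
#' @param labels A list of `schema_activation` objects, or a matrix with 9
#'   columns of ordinal codes (one row per utterance).
#' @return Numeric 9-vector of relative frequencies in [0, 1].
#' @export
schema_frequency_distribution <- function(labels) {
  m <- ordinal_label_matrix(labels)
  if (nrow(m) == 0L) stop("cannot compute frequencies over zero utterances")
  colMeans(m != 0L)
}

# internal: coerce a label collection to an utterance x 9 ordinal matrix
ordinal_label_matrix <- function(labels) {
  if (is.matrix(labels)) {
    if (ncol(labels) != 9L) stop("label matrix must have 9 columns")
    if (any(!labels %in% 0:3)) stop("ordinal codes must be in {0,1,2,3}")
    return(labels)
  }
  if (is.list(labels) && all(vapply(labels, inherits, TRUE, "schema_activation"))) {
    if (length(labels) == 0L) return(matrix(integer(), 0L, 9L))
    return(do.call(rbind, lapply(labels, `[[`, "ordinal_codes")))
  }
  stop("labels must be a list of schema_activation objects or an ",
       "utterance x 9 ordinal matrix")
}

#' Spearman rank correlation between two schema frequency profiles
#'
#' Used to compare the frequency distribution of schemas found in one
#' dataset with a reference distribution from another study. If either
#' profile is constant the rank correlation is undefined and `NA` is
#' returned (with a warning) rather than being coerced to 0.
#'
#' @param freq_a,freq_b Numeric 9-vectors of relative frequencies.
#' @return Spearman's rho in [-1, 1], or `NA_real_` if undefined.
#' @export
rank_correlation <- function(freq_a, freq_b) {
  check_schema_vector(freq_a, "freq_a")
  check_schema_vector(freq_b, "freq_b")
  if (stats::sd(freq_a) == 0 || stats::sd(freq_b) == 0) {
    warning("rank correlation undefined for a constant frequency profile")
    return(NA_real_)
  }
  stats::cor(freq_a, freq_b, method = "spearman")
}

# ---- serialization ---------------------------------------------------------

record_to_row <- function(r, max_steps) {
  steps <- c(r$downward_steps, rep(NA_character_,
                                   max_steps - length(r$downward_steps)))
  out <- data.frame(
    record_id = r$record_id, participant_id = r$participant_id,
    session_index = r$session_index, origin = r$origin,
    scenario_id = r$scenario_id, situation = r$situation,
    emotion = r$emotion, automatic_thought = r$automatic_thought,
    behavior = r$behavior, n_steps = length(r$downward_steps),
    created_at = r$created_at, stringsAsFactors = FALSE
  )
  if (max_steps > 0L) {
    step_df <- as.data.frame(as.list(steps), stringsAsFactors = FALSE)
    names(step_df) <- paste0("step_", seq_len(max_steps))
    out <- cbind(out, step_df)
  }
  out
}

#' Write thought records to CSV or JSON Lines
#'
#' CSV stores one row per record with downward steps in numbered `step_i`
#' columns; JSON Lines stores one record object per line. The round trip
#' through [read_records()] is the identity on valid record sets. Text is
#' stored verbatim (no normalization) so transcripts stay faithful.
#'
#' @param records List of `thought_record` objects.
#' @param path Output file; format chosen by extension (`.csv` or `.jsonl`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.list(records))
  fmt <- record_file_format(path)
  if (fmt == "jsonl") {
    lines <- vapply(records, function(r) {
      jsonlite::toJSON(unclass(r), auto_unbox = TRUE, null = "null",
                       na = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  max_steps <- if (length(records)) {
    max(vapply(records, function(r) length(r$downward_steps), integer(1)))
  } else 0L
  rows <- lapply(records, record_to_row, max_steps = max_steps)
  df <- if (length(rows)) do.call(rbind, rows) else
    record_to_row_header(max_steps)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

record_to_row_header <- function(max_steps) {
  cols <- c("record_id", "participant_id", "session_index", "origin",
            "scenario_id", "situation", "emotion", "automatic_thought",
            "behavior", "n_steps", "created_at")
  if (max_steps > 0L) cols <- c(cols, paste0("step_", seq_len(max_steps)))
  df <- as.data.frame(matrix(character(), 0L, length(cols)),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

record_file_format <- function(path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl"
  else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
  else stop("unsupported record file extension (use .csv or .jsonl): ", path)
}

#' Read thought records written by [write_records()]
#'
#' @param path Input file (`.csv` or `.jsonl`).
#' @return List of `thought_record` objects.
#' @export
read_records <- function(path) {
  fmt <- record_file_format(path)
  if (fmt == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    return(lapply(seq_along(lines), function(i) {
      x <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
        stop("malformed record on line ", i, ": ", conditionMessage(e))
      })
      record_from_fields(x, where = paste0("line ", i))
    }))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("record_id", "participant_id", "session_index", "origin",
                "situation", "emotion", "automatic_thought", "behavior")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("record file is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  step_cols <- grep("^step_[0-9]+$", names(df), value = TRUE)
  step_cols <- step_cols[order(as.integer(sub("step_", "", step_cols)))]
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    steps <- unlist(row[step_cols], use.names = FALSE)
    steps <- steps[!is.na(steps) & nzchar(steps)]
    record_from_fields(list(
      record_id = row$record_id, participant_id = row$participant_id,
      session_index = as.integer(row$session_index), origin = row$origin,
      scenario_id = if ("scenario_id" %in% names(row)) row$scenario_id else NULL,
      situation = row$situation, emotion = row$emotion,
      automatic_thought = row$automatic_thought, behavior = row$behavior,
      downward_steps = steps,
      created_at = if ("created_at" %in% names(row))
        as.integer(row$created_at) else 0L
    ), where = paste0("record ", row$record_id, " (row ", i, ")"))
  })
}

record_from_fields <- function(x, where) {
  scen <- x$scenario_id
  if (!is.null(scen) && (is.na(scen) || !nzchar(scen))) scen <- NULL
  steps <- x$downward_steps
  if (is.null(steps)) steps <- character()
  tryCatch(
    thought_record(
      record_id = x$record_id, participant_id = x$participant_id,
      session_index = x$session_index, origin = x$origin,
      scenario_id = scen, situation = x$situation, emotion = x$emotion,
      automatic_thought = x$automatic_thought, behavior = x$behavior,
      downward_steps = unlist(steps),
      created_at = if (is.null(x$created_at)) 0L else x$created_at
    ),
    error = function(e) stop("invalid record at ", where, ": ",
                             conditionMessage(e), call. = FALSE)
  )
}

#' Write / read ordinal schema labels as CSV
#'
#' One row per utterance: `utterance_id` plus nine ordinal columns in the
#' order of the supplied schema set.
#'
#' @param labels List of `schema_activation` objects.
#' @param path CSV path.
#' @param schemas A [schema_set()]; defaults to [default_schema_set()].
#' @return `path` invisibly (write) or a list of label rows (read).
#' @export
write_labels <- function(labels, path, schemas = default_schema_set()) {
  m <- ordinal_label_matrix(labels)
  df <- data.frame(utterance_id = vapply(labels, `[[`, character(1),
                                         "utterance_id"),
                   stringsAsFactors = FALSE)
  lab_df <- as.data.frame(m)
  names(lab_df) <- make.names(schemas$names)
  utils::write.csv(cbind(df, lab_df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, schemas = default_schema_set()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- make.names(schemas$names)
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop("label file is missing schema columns: ",
         paste(missing, collapse = ", "))
  }
  m <- as.matrix(df[, expected])
  if (any(!m %in% 0:3)) stop("label file contains codes outside {0,1,2,3}")
  list(utterance_id = df$utterance_id,
       ordinal = matrix(as.integer(m), nrow(m), 9L,
                        dimnames = list(NULL, expected)))
}
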