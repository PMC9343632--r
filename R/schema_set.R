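#' Define a set of nine core-belief schemas
#'
#' Thought-record content is scored against nine schemas: stable underlying
#' patterns of thinking (e.g. Attachment, Competence) identified in content
#' analyses of thought records from people with depression and/or anxiety.
#' All scoring, feedback and frequency machinery in this package is indexed
#' by a `schema_set`, so the axis order is fixed once and reused everywhere.
#'
#' @param names Character vector of exactly 9 unique schema names.
#' @param definitions Optional character vector of 9 one-line definitions
#'   (shown to users on request in the high-richness feedback condition).
#' @return An object of class `schema_set`.
#' @seealso [default_schema_set()]
#' @export
schema_set <- function(names, definitions = NULL) {
  if (length(names) != 9L) {
    stop("a schema_set must contain exactly 9 schemas, got ", length(names))
  }
  names <- as.character(names)
  if (anyDuplicated(names)) stop("schema names must be unique")
  if (any(!nzchar(trimws(names)))) stop("schema names must be non-empty")
  if (!is.null(definitions)) {
    if (length(definitions) != 9L) {
      stop("definitions must have length 9 (one per schema)")
    }
    definitions <- as.character(definitions)
    names(definitions) <- names
  }
  structure(list(names = names, definitions = definitions),
            class = "schema_set")
}

#' Default nine-schema set
#'
#' Six schema names are fixed by the underlying content-analysis taxonomy
#' (Attachment, Competence, Global self-evaluation, Health, Meta-cognition,
#' Others' views on self). The remaining three slots are shipped with
#' commonly used placeholder names and are expected to be overridden via
#' [schema_set()] when a canonical naming is available.
#'
#' @return A `schema_set` with 9 named schemas and short definitions.
#' @export
default_schema_set <- function() {
  schema_set(
    names = c(
      "Attachment", "Competence", "Global self-evaluation", "Health",
      "Power and control", "Meta-cognition", "Others' views on self",
      "Hopelessness", "Other people's wellbeing"
    ),
    definitions = c(
      "Fear of being alone, rejected, abandoned or unloved.",
      "Seeing oneself as failing, incompetent or inadequate.",
      "Sweeping negative judgements of one's worth as a person.",
      "Worry about illness, bodily harm or loss of health.",
      "Feeling helpless, trapped or unable to influence events.",
      "Negative beliefs about one's own thinking or coping.",
      "Concern with how one is seen and judged by other people.",
      "Expecting the future to be bleak or pointless.",
      "Worry about harm, burden or distress caused to others."
    )
  )
}

#' @export
print.schema_set <- function(x, ...) {
  cat("<schema_set> with 9 schemas:\n")
  cat(paste0("  ", seq_len(9L), ". ", x$names, collapse = "\n"), "\n")
  invisible(x)
}

# internal: validate a 9-vector aligned with a schema set
check_schema_vector <- function(v, what = "vector") {
  if (length(v) != 9L) stop(what, " must have length 9, got ", length(v))
  if (any(!is.finite(v))) stop(what, " must be finite")
  invisible(v)
}
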