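#' Situation content-label schema
#'
#' The labelling scheme applied to session-2 (personal) thought-record
#' situations: the DIAMONDS situation characteristics without Positivity
#' (participants were asked for negative situations only), plus two added
#' labels, COVID-related and the achievement-related/interpersonal
#' situation type. All labels are binomial: the situation has or does not
#' have the characteristic.
#'
#' @param labels Character vector of label names.
#' @param definitions Optional named definitions.
#' @return An object of class `label_schema`.
#' @export
label_schema <- function(labels, definitions = NULL) {
  labels <- as.character(labels)
  if (!length(labels) || anyDuplicated(labels)) {
    stop("labels must be non-empty and unique")
  }
  if ("Positivity" %in% labels) {
    stop("the Positivity characteristic is not part of this scheme ",
         "(negative situations only)")
  }
  structure(list(labels = labels, definitions = definitions),
            class = "label_schema")
}

#' @rdname label_schema
#' @export
default_label_schema <- function() {
  label_schema(
    labels = c("Achievement-related", "Interpersonal", "COVID-related",
               "Duty", "Intellect", "Adversity", "Mating", "Negativity",
               "Deception", "Sociality"),
    definitions = c(
      "Self-esteem is at risk because it is possible to perform poorly.",
      "Social situations that can affect one's self-worth.",
      "The situation mentions the COVID-19 pandemic.",
      "The situation requires carrying out a task conscientiously.",
      "The situation is cognitively stimulating.",
      "One is criticized, blamed, or dominated.",
      "Potential or actual romantic partners are involved.",
      "The situation is anxiety-inducing, stressful, or upsetting.",
      "Deception or sabotage can lead to feelings of hostility.",
      "The situation involves social interaction."
    )
  )
}

#' Validate a binary content-label matrix against a schema
#'
#' @param matrix Records x labels matrix or data.frame with 0/1 entries;
#'   column names must cover the schema's labels.
#' @param schema A [label_schema()].
#' @return The validated integer matrix with columns in schema order.
#' @export
validate_label_matrix <- function(matrix, schema = default_label_schema()) {
  m <- as.matrix(matrix)
  missing <- setdiff(schema$labels, colnames(m))
  if (length(missing)) {
    stop("label matrix is missing label column(s): ",
         paste(missing, collapse = ", "))
  }
  m <- m[, schema$labels, drop = FALSE]
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf(
      "non-binary entry %s at record %d, label '%s' (labels are has/has-not)",
      format(m[bad[1]]), rc[1], colnames(m)[rc[2]]))
  }
  storage.mode(m) <- "integer"
  m
}

#' Per-label agreement and frequency summary for two coders
#'
#' For each content label: Cohen's kappa between the two coders (interrater
#' reliability) and the mean relative frequency (MRF, percent), i.e. the
#' mean over coders of the fraction of records carrying the label. Labels
#' on which both coders are constant and identical have undefined kappa
#' (`NA`).
#'
#' @param matrix_coder1,matrix_coder2 Binary records x labels matrices over
#'   the same record set.
#' @param schema A [label_schema()].
#' @return data.frame with columns `label`, `kappa`, `mrf_percent`.
#' @export
label_summary <- function(matrix_coder1, matrix_coder2,
                          schema = default_label_schema()) {
  m1 <- validate_label_matrix(matrix_coder1, schema)
  m2 <- validate_label_matrix(matrix_coder2, schema)
  if (nrow(m1) != nrow(m2)) {
    stop("coder matrices must cover the same records")
  }
  kap <- vapply(schema$labels, function(l) {
    suppressWarnings(cohens_kappa(m1[, l], m2[, l]))
  }, numeric(1))
  mrf <- 100 * (colMeans(m1) + colMeans(m2)) / 2
  data.frame(label = schema$labels, kappa = unname(kap),
             mrf_percent = unname(mrf[schema$labels]),
             stringsAsFactors = FALSE, row.names = NULL)
}
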