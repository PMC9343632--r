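#' Validate a participant-level study table
#'
#' One row per analysed participant: the 3-level feedback-richness
#' `condition` (low/medium/high, low = reference), the `nsr`
#' (need-for-self-reflection) sum score, the `insight` sum score, the
#' `engagement` sum score, and `n_voluntary_records`, the number of thought
#' records completed in the second (personal) session. Session 2 required
#' at least one record, so counts are >= 1.
#'
#' @param table data.frame with the columns above.
#' @return The table with `condition` as a factor (low reference),
#'   invisibly classed as validated.
#' @export
validate_study_table <- function(table) {
  required <- c("condition", "nsr", "insight", "engagement",
                "n_voluntary_records")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop("study table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyNA(table[required])) stop("study table contains missing values")
  cond <- as.character(table$condition)
  if (!all(cond %in% c("low", "medium", "high"))) {
    stop("condition must be one of low/medium/high")
  }
  table$condition <- factor(cond, levels = c("low", "medium", "high"))
  if (any(table$n_voluntary_records < 1)) {
    stop("n_voluntary_records must be >= 1 (session 2 required one record)")
  }
  if (any(table$n_voluntary_records != floor(table$n_voluntary_records))) {
    stop("n_voluntary_records must be integer counts")
  }
  table
}

new_model_report <- function(name, fit, family, statistic_type,
                             transformation = NULL, extra = NULL,
                             notes = character()) {
  sm <- summary(fit)
  co <- stats::coef(sm)
  tab <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    statistic = co[, 3], p = co[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(name = name, coefficients = tab, family = family,
                 statistic_type = statistic_type,
                 n = stats::nobs(fit), df_residual = stats::df.residual(fit),
                 transformation = transformation, extra = extra,
                 notes = notes, fit = fit),
            class = "model_report")
}

#' @export
print.model_report <- function(x, digits = 3, ...) {
  cat(sprintf("<model_report '%s'> family=%s, n=%d, residual df=%d\n",
              x$name, x$family, x$n, x$df_residual))
  if (!is.null(x$transformation)) {
    cat(sprintf("  outcome Box-Cox transformed, lambda = %.2f\n",
                x$transformation$lambda))
  }
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits)
  names(tab)[names(tab) == "statistic"] <- x$statistic_type
  print(tab, row.names = FALSE)
  if (!is.null(x$extra$rate_ratio)) {
    cat(sprintf("  rate ratio per insight point: exp(b) = %.3f\n",
                x$extra$rate_ratio))
  }
  for (nt in x$notes) cat("  note: ", nt, "\n", sep = "")
  invisible(x)
}

check_condition_levels <- function(table) {
  lv <- unique(as.character(table$condition))
  if (length(lv) < 2L) {
    stop("condition factor needs at least 2 observed levels, got ",
         length(lv))
  }
  invisible(table)
}

#' Direct effect of feedback richness on the count outcome
#'
#' Poisson generalized linear model with log link:
#' `n_voluntary_records ~ condition` (treatment coding, low = reference).
#'
#' @param table A study table (see [validate_study_table()]).
#' @return A `model_report` (z statistics).
#' @export
fit_direct_count <- function(table) {
  table <- validate_study_table(table)
  check_condition_levels(table)
  notes <- character()
  if (stats::var(table$n_voluntary_records) == 0) {
    notes <- "degenerate fit: all counts identical"
  }
  fit <- stats::glm(n_voluntary_records ~ condition, data = table,
                    family = stats::poisson())
  new_model_report("direct effect on voluntary record count", fit,
                   "poisson", "z", notes = notes)
}

#' Direct effect of feedback richness on engagement
#'
#' Linear model on the Box-Cox-transformed engagement score:
#' `boxcox(engagement) ~ condition`. The transformation lambda is estimated
#' once on the engagement vector (not per model) and recorded in the
#' report.
#'
#' @param table A study table.
#' @param lambda Optional fixed Box-Cox lambda.
#' @return A `model_report` (t statistics).
#' @export
fit_direct_engagement <- function(table, lambda = NULL) {
  table <- validate_study_table(table)
  check_condition_levels(table)
  bc <- boxcox_transform(table$engagement, lambda = lambda)
  table$engagement_bc <- bc$transformed
  fit <- stats::lm(engagement_bc ~ condition, data = table)
  new_model_report("direct effect on engagement (Box-Cox scale)", fit,
                   "gaussian", "t",
                   transformation = list(type = "boxcox", lambda = bc$lambda))
}

#' a-path: effect of feedback richness on the mediator (insight)
#'
#' Linear model `insight ~ condition`.
#'
#' @param table A study table.
#' @return A `model_report` (t statistics).
#' @export
fit_apath <- function(table) {
  table <- validate_study_table(table)
  check_condition_levels(table)
  if (nrow(table) < 4L) stop("too few rows to fit the a-path model")
  fit <- stats::lm(insight ~ condition, data = table)
  new_model_report("a-path: insight ~ condition", fit, "gaussian", "t")
}

#' b-path: effect of the mediator on an outcome, controlling for condition
#'
#' For the count outcome, a Poisson GLM
#' `n_voluntary_records ~ insight + condition`; the report additionally
#' carries `exp(b_insight)`, the rate ratio per insight scale point. For
#' the engagement outcome, a linear model on the Box-Cox-transformed score.
#'
#' @param table A study table.
#' @param outcome `"count"` or `"engagement"`.
#' @param lambda Optional fixed Box-Cox lambda (engagement only).
#' @return A `model_report`.
#' @export
fit_bpath <- function(table, outcome = c("count", "engagement"),
                      lambda = NULL) {
  outcome <- match.arg(outcome)
  table <- validate_study_table(table)
  check_condition_levels(table)
  if (outcome == "count") {
    fit <- stats::glm(n_voluntary_records ~ insight + condition,
                      data = table, family = stats::poisson())
    b <- stats::coef(fit)[["insight"]]
    return(new_model_report("b-path: voluntary records ~ insight + condition",
                            fit, "poisson", "z",
                            extra = list(rate_ratio = exp(b))))
  }
  bc <- boxcox_transform(table$engagement, lambda = lambda)
  table$engagement_bc <- bc$transformed
  fit <- stats::lm(engagement_bc ~ insight + condition, data = table)
  new_model_report("b-path: engagement (Box-Cox) ~ insight + condition",
                   fit, "gaussian", "t",
                   transformation = list(type = "boxcox", lambda = bc$lambda))
}

#' Moderation of the direct effect by need for self-reflection
#'
#' Linear regression `outcome ~ condition * nsr`. Following the analysis
#' plan, the count outcome is, by default, also modelled with a linear
#' regression; a Poisson GLM variant is available via `family = "poisson"`
#' (see the methods vignette for the rationale).
#'
#' @param table A study table.
#' @param outcome `"count"` or `"engagement"`.
#' @param family `"linear"` (default) or `"poisson"` (count outcome only).
#' @param lambda Optional fixed Box-Cox lambda (engagement only).
#' @return A `model_report`.
#' @export
fit_moderation <- function(table, outcome = c("count", "engagement"),
                           family = c("linear", "poisson"), lambda = NULL) {
  outcome <- match.arg(outcome)
  family <- match.arg(family)
  table <- validate_study_table(table)
  check_condition_levels(table)
  if (stats::var(table$nsr) == 0) {
    stop("nsr is constant: the interaction model is rank-deficient")
  }
  if (outcome == "count") {
    if (family == "poisson") {
      fit <- stats::glm(n_voluntary_records ~ condition * nsr, data = table,
                        family = stats::poisson())
      return(new_model_report("moderation: voluntary records ~ condition x nsr",
                              fit, "poisson", "z"))
    }
    fit <- stats::lm(n_voluntary_records ~ condition * nsr, data = table)
    return(new_model_report("moderation: voluntary records ~ condition x nsr",
                            fit, "gaussian", "t"))
  }
  bc <- boxcox_transform(table$engagement, lambda = lambda)
  table$engagement_bc <- bc$transformed
  fit <- stats::lm(engagement_bc ~ condition * nsr, data = table)
  new_model_report("moderation: engagement (Box-Cox) ~ condition x nsr",
                   fit, "gaussian", "t",
                   transformation = list(type = "boxcox", lambda = bc$lambda))
}

sig_any <- function(report, terms_regex, alpha) {
  tab <- report$coefficients
  hit <- grepl(terms_regex, tab$term)
  any(tab$p[hit] < alpha)
}

#' Run the stepwise (Baron-Kenny) mediation analysis
#'
#' Executes the full model sequence for both outcomes: direct effects,
#' a-path, b-paths, and the moderation checks, then records the decision
#' trail: whether an a-path effect was present at the configured alpha,
#' whether mediation was pursued, and that moderated mediation is not
#' tested when mediation is absent. No model is silently dropped; every
#' fitted report is returned.
#'
#' @param table A study table.
#' @param alpha Two-sided significance level (default 0.05).
#' @param lambda Optional fixed Box-Cox lambda for engagement models.
#' @return An object of class `baron_kenny_report`: list with `models`
#'   (named list of `model_report`s), `decisions` (character trail),
#'   `alpha`.
#' @export
run_baron_kenny <- function(table, alpha = 0.05, lambda = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  table <- validate_study_table(table)
  models <- list(
    direct_count = fit_direct_count(table),
    direct_engagement = fit_direct_engagement(table, lambda = lambda),
    apath = fit_apath(table),
    bpath_count = fit_bpath(table, "count"),
    bpath_engagement = fit_bpath(table, "engagement", lambda = lambda),
    moderation_count = fit_moderation(table, "count"),
    moderation_engagement = fit_moderation(table, "engagement",
                                           lambda = lambda)
  )
  cond_rx <- "^condition"
  decisions <- character()
  a_sig <- sig_any(models$apath, cond_rx, alpha)
  decisions <- c(decisions, sprintf(
    "a-path (condition -> insight) %s at alpha = %g",
    if (a_sig) "significant" else "not significant", alpha))
  for (oc in c("count", "engagement")) {
    direct <- models[[paste0("direct_", oc)]]
    b <- models[[paste0("bpath_", oc)]]
    d_sig <- sig_any(direct, cond_rx, alpha)
    b_sig <- sig_any(b, "^insight$", alpha)
    decisions <- c(decisions, sprintf(
      "direct effect on %s %s; b-path (insight) %s", oc,
      if (d_sig) "significant" else "not significant",
      if (b_sig) "significant" else "not significant"))
    if (a_sig && b_sig) {
      decisions <- c(decisions, sprintf(
        "mediation supported for %s: test the indirect effect (see bc_bootstrap_indirect)",
        oc))
    } else {
      decisions <- c(decisions, sprintf(
        "no a-path effect%s: mediation not supported for %s; moderated mediation not tested",
        if (a_sig) " on this b-path" else "", oc))
    }
  }
  structure(list(models = models, decisions = decisions, alpha = alpha),
            class = "baron_kenny_report")
}

#' @export
print.baron_kenny_report <- function(x, ...) {
  cat("<baron_kenny_report> alpha =", x$alpha, "\n\n")
  for (m in x$models) {
    print(m)
    cat("\n")
  }
  cat("Decision trail:\n")
  cat(paste0("  - ", x$decisions, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report A `baron_kenny_report` or `model_report`.
#' @param path Optional output file.
#' @return JSON string, or `path` invisibly.
#' @export
report_to_json <- function(report, path = NULL) {
  strip <- function(m) {
    m$fit <- NULL
    unclass(m)
  }
  payload <- if (inherits(report, "baron_kenny_report")) {
    list(alpha = report$alpha, decisions = report$decisions,
         models = lapply(report$models, strip))
  } else strip(report)
  if (is.null(path)) {
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, null = "null")))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement \eqn{(p_o - p_e)/(1 - p_e)} with the
#' marginal-product definition of chance agreement. When both raters are
#' constant and identical, chance agreement is 1 and kappa is undefined;
#' `NA` is returned with a warning.
#'
#' @param labels_a,labels_b Equal-length 0/1 vectors.
#' @return Kappa in [-1, 1], or `NA_real_` when undefined.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || !length(labels_a)) {
    stop("label vectors must be non-empty and of equal length")
  }
  if (any(!labels_a %in% 0:1) || any(!labels_b %in% 0:1)) {
    stop("labels must be binary 0/1")
  }
  n <- length(labels_a)
  po <- mean(labels_a == labels_b)
  pa <- mean(labels_a)
  pb <- mean(labels_b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) {
    warning("both raters constant and identical: kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Label frequencies and inter-coder frequency agreement
#'
#' For two coders' binary label matrices (records x labels), computes each
#' label's mean relative frequency (MRF, in percent): the mean over coders
#' of the fraction of records carrying the label; plus the Pearson
#' correlation between the two coders' per-label frequency vectors.
#'
#' @param matrix_a,matrix_b Binary matrices (records x labels) with
#'   matching dimensions; column names are label names.
#' @return List with `mrf_percent` (named vector) and `frequency_r`.
#' @export
label_frequency <- function(matrix_a, matrix_b) {
  matrix_a <- as.matrix(matrix_a)
  matrix_b <- as.matrix(matrix_b)
  if (!identical(dim(matrix_a), dim(matrix_b))) {
    stop("coder matrices must have identical dimensions")
  }
  if (any(!matrix_a %in% 0:1) || any(!matrix_b %in% 0:1)) {
    stop("label matrices must be binary 0/1")
  }
  fa <- colMeans(matrix_a)
  fb <- colMeans(matrix_b)
  r <- if (stats::sd(fa) == 0 || stats::sd(fb) == 0) {
    warning("a coder's frequency vector is constant: correlation undefined")
    NA_real_
  } else {
    stats::cor(fa, fb)
  }
  list(mrf_percent = 100 * (fa + fb) / 2, frequency_r = r)
}
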