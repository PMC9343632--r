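#' Construct a Likert response matrix for one subscale
#'
#' Wraps a participants x items integer matrix with its subscale identity
#' and per-item response range. A scoreable matrix has no missing values
#' and all entries inside the range. The engagement-in-self-reflection
#' subscale uses 6 items on a 1--6 response scale, so summed scores span
#' 6--36.
#'
#' @param responses Integer matrix (participants x items).
#' @param subscale One of `need_for_self_reflection`, `insight`,
#'   `engagement`.
#' @param response_range Length-2 integer vector `(min, max)`.
#' @return An object of class `likert_matrix`.
#' @export
likert_matrix <- function(responses,
                          subscale = c("need_for_self_reflection", "insight",
                                       "engagement"),
                          response_range = c(1L, 6L)) {
  subscale <- match.arg(subscale)
  responses <- as.matrix(responses)
  if (anyNA(responses)) stop("missing responses; imputation is out of scope")
  if (any(responses != floor(responses))) stop("responses must be integers")
  if (any(responses < response_range[1] | responses > response_range[2])) {
    stop("responses outside the declared range [", response_range[1], ", ",
         response_range[2], "]")
  }
  structure(list(responses = responses, subscale = subscale,
                 response_range = as.integer(response_range)),
            class = "likert_matrix")
}

as_response_matrix <- function(m) {
  if (inherits(m, "likert_matrix")) m$responses else as.matrix(m)
}

#' Sum-score a subscale
#'
#' The items of each subscale are summed into a per-participant summary
#' score. Reverse-keyed items, if any, must be recoded via `key` before
#' summing.
#'
#' @param matrix A [likert_matrix()] (or plain matrix).
#' @param key Optional +1/-1 vector (one per item); -1 items are reflected
#'   around the response range before summing.
#' @return Numeric vector of per-participant sums.
#' @export
score_subscale <- function(matrix, key = NULL) {
  resp <- as_response_matrix(matrix)
  if (anyNA(resp)) stop("missing responses; imputation is out of scope")
  if (!is.null(key)) {
    if (length(key) != ncol(resp) || any(!key %in% c(-1, 1))) {
      stop("key must be a +1/-1 vector with one entry per item")
    }
    rng <- if (inherits(matrix, "likert_matrix")) matrix$response_range else
      range(resp)
    rev_idx <- which(key == -1)
    resp[, rev_idx] <- rng[1] + rng[2] - resp[, rev_idx]
  }
  rowSums(resp)
}

#' Cronbach's alpha with a Feldt confidence interval
#'
#' Internal-consistency reliability \eqn{\alpha = k/(k-1) (1 - \sum s_i^2 /
#' s_T^2)} where \eqn{s_i^2} are item variances and \eqn{s_T^2} the
#' variance of the total score. The confidence interval uses Feldt's
#' F-distribution method with degrees of freedom \eqn{n-1} and
#' \eqn{(n-1)(k-1)}; a nonparametric bootstrap interval is available via
#' `ci = "bootstrap"`.
#'
#' @param matrix A [likert_matrix()] or numeric matrix (participants x
#'   items), at least 2 items and 3 participants.
#' @param conf_level Confidence level (default 0.95).
#' @param ci `"feldt"` or `"bootstrap"`.
#' @param boot_B Bootstrap resamples when `ci = "bootstrap"`.
#' @return List with `alpha`, `ci` (length 2), `method`, `n`, `k`. If the
#'   total-score variance is zero, `alpha` is `NA` with a warning.
#' @export
cronbach_alpha <- function(matrix, conf_level = 0.95,
                           ci = c("feldt", "bootstrap"), boot_B = 2000L) {
  ci <- match.arg(ci)
  resp <- as_response_matrix(matrix)
  n <- nrow(resp)
  k <- ncol(resp)
  if (k < 2L) stop("alpha requires at least 2 items")
  if (n < 3L) stop("alpha requires at least 3 participants")
  alpha_of <- function(x) {
    total_var <- stats::var(rowSums(x))
    if (total_var == 0) return(NA_real_)
    k / (k - 1) * (1 - sum(apply(x, 2L, stats::var)) / total_var)
  }
  a <- alpha_of(resp)
  if (is.na(a)) {
    warning("total-score variance is zero; alpha is undefined")
    return(list(alpha = NA_real_, ci = c(NA_real_, NA_real_),
                method = ci, n = n, k = k))
  }
  gamma <- 1 - conf_level
  interval <- if (ci == "feldt") {
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    c(1 - (1 - a) * stats::qf(1 - gamma / 2, df1, df2),
      1 - (1 - a) * stats::qf(gamma / 2, df1, df2))
  } else {
    boot <- vapply(seq_len(boot_B), function(b) {
      alpha_of(resp[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
    stats::quantile(boot, c(gamma / 2, 1 - gamma / 2), na.rm = TRUE,
                    names = FALSE)
  }
  list(alpha = a, ci = interval, method = ci, n = n, k = k)
}

boxcox_profile_loglik <- function(lambda, y) {
  n <- length(y)
  z <- if (abs(lambda) < 1e-5) log(y) else (y^lambda - 1) / lambda
  sigma2 <- sum((z - mean(z))^2) / n
  -n / 2 * log(sigma2) + (lambda - 1) * sum(log(y))
}

#' Box-Cox transformation with maximum-likelihood lambda
#'
#' Transforms a positive outcome with \eqn{(y^\lambda - 1)/\lambda}
#' (\eqn{\log y} at \eqn{\lambda = 0}), choosing \eqn{\lambda} to maximize
#' the profile log-likelihood under a normal model, or applying a supplied
#' \eqn{\lambda}. Used for the ceiling-skewed engagement score before
#' linear modelling.
#'
#' @param y Positive numeric vector.
#' @param lambda Optional fixed lambda; when `NULL` (default) the MLE over
#'   `interval` is used.
#' @param interval Search interval for the MLE.
#' @return List with `transformed`, `lambda`, and the profile log-likelihood
#'   at the optimum (`loglik`).
#' @export
boxcox_transform <- function(y, lambda = NULL, interval = c(-5, 10)) {
  if (any(!is.finite(y))) stop("y must be finite")
  if (any(y <= 0)) {
    stop("Box-Cox requires strictly positive values; consider adding a ",
         "shift constant before transforming")
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(boxcox_profile_loglik, interval = interval, y = y,
                           maximum = TRUE, tol = 1e-6)
    lambda <- opt$maximum
    ll <- opt$objective
  } else {
    ll <- boxcox_profile_loglik(lambda, y)
  }
  z <- if (abs(lambda) < 1e-5) log(y) else (y^lambda - 1) / lambda
  list(transformed = z, lambda = lambda, loglik = ll)
}
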