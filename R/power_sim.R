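#' Configuration for the mediation power simulation
#'
#' The design under study: a 3-level feedback-richness factor (balanced
#' arms), a continuous mediator (insight), and a Poisson count outcome
#' (voluntary thought records). Effect sizes are given as per-path
#' explained variance: `a_path_R2` is the fraction of mediator variance
#' explained by condition, `b_path_R2` the fraction of latent
#' linear-predictor variance explained by the mediator given condition.
#' The default 0.13 on both paths is the medium effect the design was
#' powered for.
#'
#' @param n_grid Ascending sample sizes to evaluate.
#' @param replicates Simulation replicates per grid point.
#' @param bootstrap_B Bootstrap resamples per replicate.
#' @param alpha Two-sided test level.
#' @param a_path_R2,b_path_R2 Per-path explained variance in (0, 1).
#' @param target_power Power to reach (default 0.80).
#' @param baseline_rate Marginal Poisson mean of the count outcome
#'   (default 1.6, matching the observed session-2 record mean).
#' @param contrast Condition contrast carrying the indirect effect:
#'   `"high_vs_low"` (default) or `"medium_vs_low"`.
#' @param seed Integer master seed; every replicate derives its own
#'   substream from it.
#' @return An object of class `power_config`.
#' @export
power_config <- function(n_grid = c(250, 275, 300, 306, 325, 350),
                         replicates = 1000L, bootstrap_B = 1000L,
                         alpha = 0.05, a_path_R2 = 0.13, b_path_R2 = 0.13,
                         target_power = 0.80, baseline_rate = 1.6,
                         contrast = c("high_vs_low", "medium_vs_low"),
                         seed = 1L) {
  contrast <- match.arg(contrast)
  if (is.unsorted(n_grid)) stop("n_grid must be sorted ascending")
  if (any(n_grid < 3)) stop("n must be at least 3 (one participant per arm)")
  if (replicates < 1L || bootstrap_B < 1L) {
    stop("replicates and bootstrap_B must be >= 1")
  }
  for (r2 in c(a_path_R2, b_path_R2)) {
    if (r2 < 0 || r2 >= 1) stop("R2 values must lie in [0, 1)")
  }
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  structure(list(n_grid = as.integer(n_grid),
                 replicates = as.integer(replicates),
                 bootstrap_B = as.integer(bootstrap_B), alpha = alpha,
                 a_path_R2 = a_path_R2, b_path_R2 = b_path_R2,
                 target_power = target_power, baseline_rate = baseline_rate,
                 contrast = contrast, seed = as.integer(seed)),
            class = "power_config")
}

#' Desk-scale preset of the power configuration
#'
#' 200 replicates with 500 bootstrap resamples: enough Monte-Carlo
#' precision (SE of a power estimate near 0.8 is about 0.028) for a quick
#' single-CPU run.
#'
#' @param ... Overrides passed to [power_config()].
#' @return A `power_config`.
#' @export
power_config_fast <- function(...) {
  args <- utils::modifyList(list(replicates = 200L, bootstrap_B = 500L),
                            list(...))
  do.call(power_config, args)
}

# deterministic substream seed below 2^31
substream_seed <- function(seed, n, r) {
  (as.numeric(seed) * 1103515245 + n * 12289 + r * 7919) %% 2147483629
}

# solve generator coefficients from the configured R2 values.
# mediator: M = mu[arm] + e, e ~ N(0,1); arm means are equally spaced
# (-d, 0, d) so that Var(mu) = 2 d^2 / 3 gives the requested a-path R2.
# latent log-rate: eta = b0 + b1 M + u, u ~ N(0,1); partial R2 of M given
# condition is b1^2 Var(M | cond) / (b1^2 Var(M | cond) + 1) with
# Var(M | cond) = 1, giving b1. b0 is solved in closed form so the marginal
# Poisson mean equals baseline_rate (lognormal moments).
mediation_coefficients <- function(config) {
  d <- sqrt(3 * config$a_path_R2 / (2 * (1 - config$a_path_R2)))
  mu <- c(low = -d, medium = 0, high = d)
  b1 <- sqrt(config$b_path_R2 / (1 - config$b_path_R2))
  mean_exp_eta0 <- mean(exp(b1 * mu + b1^2 / 2)) * exp(1 / 2)
  b0 <- log(config$baseline_rate) - log(mean_exp_eta0)
  list(arm_means = mu, b0 = b0, b1 = b1, sigma_m = 1, sigma_u = 1)
}

#' Simulate one dataset from the mediation design
#'
#' Balanced 3-arm condition, arm-dependent Gaussian mediator, and a Poisson
#' count outcome whose log rate is linear in the mediator plus latent
#' Gaussian noise, with coefficients solved from the configured per-path
#' explained variances (see [power_config()]).
#'
#' @param n Total sample size (split as evenly as possible over 3 arms).
#' @param config A `power_config`.
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return data.frame with columns `condition`, `mediator`, `outcome`.
#' @export
simulate_mediation_dataset <- function(n, config = power_config(),
                                       seed = NULL) {
  if (n < 3) stop("n must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  cf <- mediation_coefficients(config)
  base <- n %/% 3L
  sizes <- base + (seq_len(3L) <= n %% 3L)
  condition <- factor(rep(c("low", "medium", "high"), times = sizes),
                      levels = c("low", "medium", "high"))
  mediator <- cf$arm_means[as.integer(condition)] +
    stats::rnorm(n, sd = cf$sigma_m)
  eta <- cf$b0 + cf$b1 * mediator + stats::rnorm(n, sd = cf$sigma_u)
  outcome <- stats::rpois(n, exp(pmin(eta, 30)))
  data.frame(condition = condition, mediator = unname(mediator),
             outcome = outcome)
}

# ---- fast fixed-design fitters (used inside the bootstrap loop) -----------

fast_lm_coef <- function(X, y) {
  stats::.lm.fit(X, y)$coefficients
}

fast_poisson_coef <- function(X, y, max_iter = 50L, tol = 1e-9) {
  beta <- c(log(mean(y) + 1e-8), rep(0, ncol(X) - 1L))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(pmin(eta, 30))
    score <- crossprod(X, y - mu)
    info <- crossprod(X, X * mu)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) return(rep(NA_real_, ncol(X)))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

indirect_estimate <- function(Xa, Xb, mediator, outcome, contrast_col) {
  a <- fast_lm_coef(Xa, mediator)[contrast_col]
  bcoef <- fast_poisson_coef(Xb_with_mediator(Xb, mediator), outcome)
  a * bcoef[2L]
}

Xb_with_mediator <- function(Xb, mediator) {
  Xb[, 2L] <- mediator
  Xb
}

#' Bias-corrected bootstrap CI for the indirect effect
#'
#' Per bootstrap resample (rows with replacement): refit the a-path linear
#' model (mediator ~ condition) and the b-path Poisson model
#' (outcome ~ mediator + condition); the indirect effect is the product of
#' the chosen condition contrast's a coefficient and the mediator's b
#' coefficient. The interval is the bias-corrected percentile interval:
#' with z0 the normal quantile of the fraction of bootstrap estimates below
#' the point estimate, the CI takes the bootstrap quantiles at
#' `pnorm(2 z0 +/- z_(1-alpha/2))`. Resamples that drop an arm or leave
#' the mediator constant are redrawn (bounded).
#'
#' @param data data.frame with columns `condition` (3-level factor),
#'   `mediator`, `outcome` (as from [simulate_mediation_dataset()]); any
#'   study table with those semantics works.
#' @param B Number of bootstrap resamples (>= 100).
#' @param alpha Interval level is `1 - alpha`.
#' @param contrast `"high_vs_low"` or `"medium_vs_low"`.
#' @param max_redraws Bound on degenerate-resample redraws.
#' @return List with `indirect` (point estimate), `ci`, `z0`, `a`, `b`,
#'   `n_redraws`, `boot` (bootstrap estimates).
#' @export
bc_bootstrap_indirect <- function(data, B = 1000L, alpha = 0.05,
                                  contrast = c("high_vs_low",
                                               "medium_vs_low"),
                                  max_redraws = 1000L) {
  contrast <- match.arg(contrast)
  if (B < 100L) stop("B must be at least 100")
  condition <- factor(as.character(data$condition),
                      levels = c("low", "medium", "high"))
  n <- nrow(data)
  med <- as.numeric(data$mediator)
  out <- as.numeric(data$outcome)
  Xa <- cbind(1, condition == "medium", condition == "high")
  storage.mode(Xa) <- "double"
  Xb <- cbind(Xa[, 1L], med, Xa[, 2:3])
  contrast_col <- if (contrast == "high_vs_low") 3L else 2L
  a_hat <- fast_lm_coef(Xa, med)[contrast_col]
  b_hat <- fast_poisson_coef(Xb, out)[2L]
  point <- a_hat * b_hat
  cond_int <- as.integer(condition)
  boot <- numeric(B)
  n_redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      ci_tab <- tabulate(cond_int[idx], 3L)
      if (all(ci_tab >= 2L) && stats::var(med[idx]) > 0) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws) {
        stop("too many degenerate bootstrap resamples (single-arm draws)")
      }
    }
    est <- indirect_estimate(Xa[idx, , drop = FALSE],
                             Xb[idx, , drop = FALSE],
                             med[idx], out[idx], contrast_col)
    boot[b] <- est
  }
  ok <- is.finite(boot)
  boot_ok <- boot[ok]
  prop_below <- mean(boot_ok < point)
  # clamp so z0 stays finite when the point estimate is extreme
  prop_below <- min(max(prop_below, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop_below)
  zc <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  probs <- stats::pnorm(2 * z0 + zc)
  ci <- unname(stats::quantile(boot_ok, probs, type = 7))
  list(indirect = unname(point), ci = ci, z0 = z0, a = unname(a_hat),
       b = unname(b_hat), n_redraws = n_redraws, boot = boot)
}

#' Estimate power of the bias-corrected bootstrap mediation test
#'
#' The power at sample size `n` is the fraction of simulation replicates
#' whose BC bootstrap interval for the indirect effect excludes zero.
#'
#' @param n Sample size.
#' @param config A `power_config`.
#' @return List with `power`, `se` (binomial Monte-Carlo SE), `n`,
#'   `replicates`.
#' @export
estimate_power <- function(n, config = power_config()) {
  R <- config$replicates
  rejections <- logical(R)
  for (r in seq_len(R)) {
    dat <- simulate_mediation_dataset(
      n, config, seed = substream_seed(config$seed, n, r))
    res <- bc_bootstrap_indirect(dat, B = config$bootstrap_B,
                                 alpha = config$alpha,
                                 contrast = config$contrast)
    rejections[r] <- res$ci[1] > 0 || res$ci[2] < 0
  }
  p <- mean(rejections)
  list(power = p, se = sqrt(p * (1 - p) / R), n = n, replicates = R)
}

#' Find the minimum sample size reaching the target power
#'
#' Evaluates the power curve over the configured grid and returns the
#' smallest grid point whose estimated power reaches the target. If the
#' target is not reached on the grid, `min_n` is `NA` and the message says
#' to extend the grid (no exception is thrown).
#'
#' @param config A `power_config`.
#' @param verbose Print per-n progress.
#' @return An object of class `power_result`: list with `min_n`,
#'   `power_curve` (data.frame n/power/se), `target_power`, `config`,
#'   `message`.
#' @export
find_min_n <- function(config = power_config(), verbose = FALSE) {
  curve <- data.frame(n = integer(), power = numeric(), se = numeric())
  for (n in config$n_grid) {
    est <- estimate_power(n, config)
    curve <- rbind(curve, data.frame(n = n, power = est$power, se = est$se))
    if (verbose) {
      message(sprintf("n = %4d: power = %.3f (SE %.3f)", n, est$power,
                      est$se))
    }
  }
  reached <- curve$n[curve$power >= config$target_power]
  min_n <- if (length(reached)) min(reached) else NA_integer_
  msg <- if (is.na(min_n)) {
    sprintf("target power %.2f not reached on the grid; increase the grid",
            config$target_power)
  } else {
    sprintf("smallest grid n with power >= %.2f: %d", config$target_power,
            min_n)
  }
  structure(list(min_n = min_n, power_curve = curve,
                 target_power = config$target_power, config = config,
                 message = msg),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("<power_result>", x$message, "\n")
  print(x$power_curve, row.names = FALSE)
  invisible(x)
}
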