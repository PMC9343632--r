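# quick structural-equation table with known coefficients (plain Poisson,
# no truncation, so GLM coefficients are directly recoverable)
sim_table <- function(n, a = c(0, 0, 0), b_count = 0, log_rr_cond = c(0, 0),
                      base_rate = 1.5, seed = 1) {
  set.seed(seed)
  condition <- factor(rep(c("low", "medium", "high"), length.out = n),
                      levels = c("low", "medium", "high"))
  ci <- as.integer(condition)
  insight <- 26 + a[ci] + rnorm(n, sd = 4)
  eta <- log(base_rate) + b_count * (insight - 26) +
    c(0, log_rr_cond)[ci]
  counts <- rpois(n, exp(eta)) + 1L  # shift keeps the >= 1 invariant
  data.frame(condition = condition, nsr = round(runif(n, 10, 34)),
             insight = insight,
             engagement = pmin(pmax(round(26 + 0.4 * (insight - 26) +
                                            rnorm(n, sd = 3)), 6), 36),
             n_voluntary_records = counts)
}

test_that("study tables are validated with informative errors", {
  tab <- sim_table(30)
  expect_s3_class(validate_study_table(tab)$condition, "factor")
  bad <- tab
  bad$insight <- NULL
  expect_error(validate_study_table(bad), "insight")
  bad2 <- tab
  bad2$n_voluntary_records[1] <- 0
  expect_error(validate_study_table(bad2), ">= 1")
  bad3 <- tab
  bad3$condition <- as.character(bad3$condition)
  bad3$condition[1] <- "none"
  expect_error(validate_study_table(bad3), "low/medium/high")
})

test_that("the direct count model recovers a known rate ratio", {
  # arm 'medium' at exactly 2x the low rate, large n (shift-free generator)
  set.seed(10)
  n <- 30000
  condition <- factor(rep(c("low", "medium", "high"), length.out = n),
                      levels = c("low", "medium", "high"))
  mu <- c(1.5, 3.0, 1.5)[as.integer(condition)]
  tab <- data.frame(condition = condition, nsr = 20, insight = 26,
                    engagement = 25,
                    n_voluntary_records = rpois(n, mu) + 1L)
  # fit on the untruncated count via the same engine the report uses
  fit <- glm(I(n_voluntary_records - 1L) ~ condition, data = tab,
             family = poisson())
  expect_equal(unname(coef(fit)["conditionmedium"]), log(2),
               tolerance = 0.05)

  rep_count <- fit_direct_count(tab)
  expect_identical(rep_count$family, "poisson")
  expect_identical(rep_count$statistic_type, "z")
  expect_identical(nrow(rep_count$coefficients), 3L)

  one_arm <- tab[tab$condition == "low", ]
  expect_error(fit_direct_count(one_arm), "2 observed levels")
})

test_that("null generators produce null coefficient estimates at the right rate", {
  # under a zero condition effect, condition coefficients stay within 3 SE
  # of 0 in at least 95% of replicates
  ok_count <- ok_apath <- logical(60)
  for (r in seq_len(60)) {
    tab <- sim_table(240, seed = 100 + r)
    co <- fit_direct_count(tab)$coefficients
    ok_count[r] <- all(abs(co$estimate[-1] / co$se[-1]) < 3)
    ca <- fit_apath(tab)$coefficients
    ok_apath[r] <- all(abs(ca$estimate[-1] / ca$se[-1]) < 3)
  }
  expect_gte(mean(ok_count), 0.95)
  expect_gte(mean(ok_apath), 0.95)
})

test_that("the a-path model recovers a known insight shift", {
  tab <- sim_table(6000, a = c(0, 1.5, 3), seed = 21)
  rep_a <- fit_apath(tab)
  co <- rep_a$coefficients
  expect_equal(co$estimate[co$term == "conditionmedium"], 1.5,
               tolerance = 0.35)
  expect_equal(co$estimate[co$term == "conditionhigh"], 3, tolerance = 0.35)
  expect_error(fit_apath(sim_table(30)[1:2, ]), "2 observed levels|too few")
})

test_that("the b-path rate ratio is recovered within its confidence interval", {
  # generator: each insight point multiplies the rate by 1.05
  set.seed(31)
  n <- 5000
  condition <- factor(rep(c("low", "medium", "high"), length.out = n),
                      levels = c("low", "medium", "high"))
  insight <- 26 + rnorm(n, sd = 4)
  counts <- rpois(n, exp(log(1.5) + log(1.05) * (insight - 26)))
  tab <- data.frame(condition = condition, nsr = 20, insight = insight,
                    engagement = 25, n_voluntary_records = counts + 1L)
  fit <- glm(I(n_voluntary_records - 1L) ~ insight + condition, data = tab,
             family = poisson())
  rr <- exp(unname(coef(fit)["insight"]))
  expect_gt(rr, 1.03)
  expect_lt(rr, 1.07)

  rep_b <- fit_bpath(tab, "count")
  expect_false(is.null(rep_b$extra$rate_ratio))
  expect_equal(rep_b$extra$rate_ratio,
               exp(rep_b$coefficients$estimate[
                 rep_b$coefficients$term == "insight"]))

  # permuting insight across rows destroys the association
  hits <- vapply(1:40, function(r) {
    tab2 <- tab
    set.seed(500 + r)
    tab2$insight <- sample(tab2$insight)
    co <- fit_bpath(tab2, "count")$coefficients
    abs(co$estimate[co$term == "insight"] / co$se[co$term == "insight"]) < 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("engagement models carry the Box-Cox lambda in the report", {
  tab <- sim_table(400, seed = 7)
  rep_e <- fit_direct_engagement(tab)
  expect_identical(rep_e$transformation$type, "boxcox")
  expect_true(is.finite(rep_e$transformation$lambda))
  rep_b <- fit_bpath(tab, "engagement", lambda = rep_e$transformation$lambda)
  expect_equal(rep_b$transformation$lambda, rep_e$transformation$lambda)
  expect_identical(rep_b$statistic_type, "t")
})

test_that("moderation models detect a constructed crossover interaction", {
  set.seed(41)
  n <- 4000
  condition <- factor(rep(c("low", "medium", "high"), length.out = n),
                      levels = c("low", "medium", "high"))
  nsr <- round(runif(n, 10, 34))
  nsr_c <- nsr - mean(nsr)
  eng <- 20 + ifelse(condition == "high", 0.8, 0) * nsr_c + rnorm(n, sd = 3)
  tab <- data.frame(condition = condition, nsr = nsr, insight = 26,
                    engagement = pmin(pmax(round(eng), 6), 36),
                    n_voluntary_records = rpois(n, 1.5) + 1L)
  rep_m <- fit_moderation(tab, "engagement", lambda = 1)
  co <- rep_m$coefficients
  inter <- co[co$term == "conditionhigh:nsr", ]
  expect_lt(inter$p, 1e-6)
  null_inter <- co[co$term == "conditionmedium:nsr", ]
  expect_gt(null_inter$p, 0.001)

  # count outcome defaults to the linear model, Poisson behind the flag
  rep_lin <- fit_moderation(tab, "count")
  expect_identical(rep_lin$family, "gaussian")
  rep_poi <- fit_moderation(tab, "count", family = "poisson")
  expect_identical(rep_poi$family, "poisson")

  tab$nsr <- 20
  expect_error(fit_moderation(tab, "engagement"), "constant")
})

test_that("the stepwise mediation report keeps a complete decision trail", {
  # no a-path effect: mediation not supported, moderated mediation not tested
  tab0 <- sim_table(600, seed = 51)
  rep0 <- run_baron_kenny(tab0)
  expect_length(rep0$models, 7L)
  expect_true(any(grepl("moderated mediation not tested",
                        rep0$decisions)))
  expect_true(any(grepl("a-path .* not significant", rep0$decisions)))

  # strong full mediation: every step significant at alpha
  set.seed(52)
  n <- 3000
  condition <- factor(rep(c("low", "medium", "high"), length.out = n),
                      levels = c("low", "medium", "high"))
  ci <- as.integer(condition)
  insight <- 22 + c(0, 2, 4)[ci] + rnorm(n, sd = 3)
  counts <- rpois(n, exp(log(1.4) + 0.08 * (insight - 22)))
  eng <- pmin(pmax(round(20 + 0.8 * (insight - 22) + rnorm(n, 0, 3)), 6), 36)
  tabf <- data.frame(condition = condition, nsr = round(runif(n, 10, 34)),
                     insight = insight, engagement = eng,
                     n_voluntary_records = counts + 1L)
  repf <- run_baron_kenny(tabf)
  expect_true(any(grepl("a-path .* significant", repf$decisions)))
  expect_true(any(grepl("mediation supported", repf$decisions)))

  # alpha = 0: nothing significant, trail still complete
  repz <- run_baron_kenny(tab0, alpha = 0)
  expect_length(repz$models, 7L)
  expect_false(any(grepl("mediation supported", repz$decisions)))
  expect_gte(length(repz$decisions), 5L)

  js <- report_to_json(repf)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$alpha, 0.05)
  expect_length(parsed$models, 7L)
})

test_that("Cohen's kappa matches the hand-computed 2x2 oracle", {
  # table (a, b, c, d) = (40, 10, 10, 40): po = .8, pe = .5, kappa = .6
  a_lab <- c(rep(1, 50), rep(0, 50))
  b_lab <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  expect_equal(cohens_kappa(a_lab, b_lab), 0.6)

  v <- rep(c(0, 1), 10)
  expect_equal(cohens_kappa(v, v), 1)

  set.seed(61)
  x <- rbinom(20000, 1, 0.4)
  y <- rbinom(20000, 1, 0.4)
  expect_lt(abs(cohens_kappa(x, y)), 0.03)

  expect_warning(k <- cohens_kappa(rep(1, 5), rep(1, 5)), "undefined")
  expect_true(is.na(k))
  expect_error(cohens_kappa(c(0, 1), c(0, 2)), "binary")
  expect_error(cohens_kappa(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("label frequencies average the two coders and correlate profiles", {
  ones <- matrix(1, 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_warning(resn <- label_frequency(ones, ones), "constant")
  expect_equal(unname(resn$mrf_percent), rep(100, 3))

  # hand-counted 5-record fixture
  m1 <- cbind(A = c(1, 1, 0, 0, 0), B = c(1, 0, 1, 0, 1))
  m2 <- cbind(A = c(1, 0, 0, 0, 0), B = c(1, 1, 1, 0, 1))
  res <- label_frequency(m1, m2)
  expect_equal(unname(res$mrf_percent["A"]), 100 * (0.4 + 0.2) / 2)
  expect_equal(unname(res$mrf_percent["B"]), 100 * (0.6 + 0.8) / 2)
  expect_equal(res$frequency_r, cor(c(0.4, 0.6), c(0.2, 0.8)))

  # identical coders (with non-constant frequency profiles) agree perfectly
  m3 <- cbind(A = c(1, 0, 1, 0), B = c(0, 0, 1, 0))
  expect_equal(label_frequency(m3, m3)$frequency_r, 1)
})
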