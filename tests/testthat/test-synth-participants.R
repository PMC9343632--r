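test_that("persona scripts honour stop behaviour and depth distributions", {
  p_stop <- persona_config(stop_behavior = 1)
  for (i in 1:5) {
    st <- complete_session(2, "low", p_stop, seed = i)
    expect_length(st$completed_records[[1]]$downward_steps, 0L)
  }

  p_four <- persona_config(chain_depth_distribution = function(k) rep(4L, k))
  st4 <- complete_session(2, "low", p_four, seed = 3, n_records = 2)
  for (rec in st4$completed_records) {
    expect_length(rec$downward_steps, 4L)
  }
})

test_that("geometric chain depths have the configured mean", {
  p <- persona_config(chain_depth_distribution = 3)
  set.seed(9)
  depths <- numeric(1000)
  for (i in seq_len(1000)) {
    script <- generate_transcript_script(p, 2, n_records = 1)
    # steps = turns minus 4 fields, stop token, "ok", "no"
    depths[i] <- length(script) - 7L
  }
  expect_equal(mean(depths), 3, tolerance = 0.2 / 3)
})

test_that("labelled corpora are single-schema by construction and follow the mixture", {
  single <- single_schema_persona(5)
  corp <- generate_labelled_corpus(single, 200, seed = 2)
  expect_true(all(corp$ordinal[, 5] > 0))
  expect_true(all(corp$ordinal[, -5] == 0))

  w <- c(0.5, 0.3, 0.2, rep(0, 6))
  corp2 <- generate_labelled_corpus(persona_config(schema_profile = w),
                                    5000, seed = 3)
  freq <- tabulate(corp2$schema_idx, 9) / 5000
  expect_true(all(abs(freq[1:3] - w[1:3]) < 0.03))
  expect_true(all(freq[4:9] == 0))

  expect_error(generate_labelled_corpus(list(), 10), "at least one persona")
})

test_that("Likert generation hits its reliability target after discretization", {
  m0 <- generate_likert(10000, 6, target_alpha = 0, seed = 4)
  expect_lt(abs(cronbach_alpha(m0)$alpha), 0.05)

  m85 <- generate_likert(10000, 6, target_alpha = 0.85, seed = 5)
  expect_equal(cronbach_alpha(m85)$alpha, 0.85, tolerance = 0.03 / 0.85)

  m75 <- generate_likert(10000, 6, target_alpha = 0.75, seed = 6)
  expect_equal(cronbach_alpha(m75)$alpha, 0.75, tolerance = 0.03 / 0.75)

  expect_error(generate_likert(1, 6), "at least 2")
  expect_error(generate_likert(10, 6, target_alpha = 1), "\\[0, 1\\)")
  # responses respect the declared range
  expect_true(all(m85$responses %in% 1:6))
})

test_that("study tables satisfy invariants and are seed-deterministic", {
  cfg <- study_gen_config(n = 300, seed = 8)
  tab <- generate_study_table(cfg)
  expect_identical(nrow(tab), 300L)
  expect_true(all(tab$n_voluntary_records >= 1))
  expect_true(all(tab$engagement >= 6 & tab$engagement <= 36))
  expect_s3_class(tab$condition, "factor")
  # minimization keeps within-bucket arm spread at <= 1
  spread <- tapply(seq_len(nrow(tab)), tab$nsr_bucket, function(i) {
    counts <- table(tab$condition[i])
    max(counts) - min(counts)
  })
  expect_true(all(spread <= 1))
  expect_identical(generate_study_table(cfg), tab)
  expect_false(identical(generate_study_table(study_gen_config(n = 300,
                                                               seed = 9)),
                         tab))
})

test_that("configured b-path effects are recovered from generated tables", {
  cfg <- study_gen_config(n = 5000, b_count = 0.05, b_engagement = 0.6,
                          count_base_rate = 1.4, seed = 10)
  tab <- generate_study_table(cfg)
  rep_b <- fit_bpath(tab, "count")
  co <- rep_b$coefficients
  est <- co$estimate[co$term == "insight"]
  se <- co$se[co$term == "insight"]
  # truncation at 1 attenuates the plain-Poisson coefficient; the recovered
  # effect must still be positive and of the configured order
  expect_gt(est - 2 * se, 0.01)
  expect_lt(est, 0.08)

  rep_e <- fit_bpath(tab, "engagement", lambda = 1)
  coe <- rep_e$coefficients
  expect_equal(coe$estimate[coe$term == "insight"], 0.6, tolerance = 0.15)
})

test_that("null study tables yield null analysis results", {
  sig <- numeric(0)
  for (r in 1:15) {
    tab <- generate_study_table(study_gen_config(n = 250, seed = 400 + r))
    rep_a <- fit_apath(tab)
    co <- rep_a$coefficients
    sig <- c(sig, co$p[grepl("^condition", co$term)])
  }
  # two-sided p-values under the null: roughly uniform, ~5% below .05
  expect_lt(mean(sig < 0.05), 0.18)
  expect_gt(mean(sig), 0.3)
})

test_that("a high ceiling makes engagement negatively skewed", {
  cfg <- study_gen_config(n = 4000, engagement_mean = 33, seed = 12)
  tab <- generate_study_table(cfg)
  eng <- tab$engagement
  skew <- mean((eng - mean(eng))^3) / sd(eng)^3
  expect_lt(skew, -0.2)
  # and the Box-Cox MLE moves above 1, as for the real measure
  expect_gt(boxcox_transform(eng)$lambda, 1)
})

test_that("scripted personas drive every module end to end", {
  sc <- train_baseline_scorer(training_corpus(300, seed = 20))
  for (i in 1:5) {
    persona <- persona_config(schema_profile = runif(9),
                              chain_depth_distribution = 2)
    st <- complete_session(2, "high", persona, seed = 30 + i, n_records = 2)
    expect_identical(st$phase, "closing")
    recs <- st$completed_records
    vecs <- lapply(recs, function(r) score_record(sc, r))
    bundle <- compose_feedback("high", recs, scorer = sc)
    expect_identical(bundle$spider$n_previous, length(recs) - 1L)
    expect_true(all(unlist(vecs) >= 0 & unlist(vecs) <= 1))
  }
})
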