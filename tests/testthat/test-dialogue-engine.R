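test_that("session 1 starts with onboarding and queues one scenario per category", {
  res <- start_session(1, "low", seed = 7)
  st <- res$state
  expect_s3_class(st, "dialogue_state")
  expect_identical(st$phase, "scenario_presentation")
  expect_length(st$scenario_queue, 2L)
  lib <- default_scenario_library()
  cats <- lib$category[match(st$scenario_queue, lib$scenario_id)]
  expect_setequal(cats, c("interpersonal", "achievement"))
  expect_match(res$messages[1], "Luca")
})

test_that("session 2 opens with welcome-back and goes straight to the record", {
  res <- start_session(2, "high", seed = 7)
  expect_identical(res$state$phase, "ask_situation")
  expect_length(res$state$scenario_queue, 0L)
  expect_match(res$messages[1], "Welcome back")
})

test_that("malformed scenario libraries are configuration errors", {
  lib <- default_scenario_library()
  expect_error(start_session(1, "low", lib[-1, ], seed = 1), "exactly 5")
  lib2 <- lib
  lib2$category[1] <- "achievement"
  expect_error(start_session(1, "low", lib2, seed = 1), "exactly 5")
  lib3 <- lib
  lib3$scenario_id[2] <- lib3$scenario_id[1]
  expect_error(start_session(1, "low", lib3, seed = 1), "unique")
})

test_that("scenario selection is seed-deterministic, cross-category and uniform", {
  lib <- default_scenario_library()
  set.seed(99)
  p1 <- select_scenarios(lib)
  set.seed(99)
  p2 <- select_scenarios(lib)
  expect_identical(p1, p2)

  n_draws <- 10000L
  picks <- matrix("", n_draws, 2L)
  set.seed(5)
  for (i in seq_len(n_draws)) picks[i, ] <- select_scenarios(lib)
  cats <- matrix(lib$category[match(picks, lib$scenario_id)], n_draws, 2L)
  expect_true(all(cats[, 1] != cats[, 2]))
  inter_ids <- lib$scenario_id[lib$category == "interpersonal"]
  inter_picks <- picks[cats == "interpersonal"]
  freqs <- table(factor(inter_picks, levels = inter_ids)) / n_draws
  expect_true(all(abs(freqs - 0.2) < 0.02))
  # presentation order of the two categories is itself randomized
  expect_gt(mean(cats[, 1] == "interpersonal"), 0.45)
  expect_lt(mean(cats[, 1] == "interpersonal"), 0.55)
})

test_that("a scripted session fills slots in order and captures the arrow chain", {
  res <- start_session(2, "low", seed = 3)
  script <- c("my friend ignored my message", "sad and hurt",
              "she does not care about me",
              "i stopped texting anyone",
              "it means i am easy to forget",
              "people will always leave me",
              "i will end up alone",
              "done", "ok", "no")
  st <- run_script(res$state, script)
  expect_identical(st$phase, "closing")
  expect_length(st$completed_records, 1L)
  rec <- st$completed_records[[1]]
  expect_identical(rec$situation, script[1])
  expect_identical(rec$emotion, script[2])
  expect_identical(rec$automatic_thought, script[3])
  expect_identical(rec$behavior, script[4])
  expect_identical(rec$downward_steps, script[5:7])
  expect_identical(rec$origin, "personal")
})

test_that("session 1 cannot refuse the second scenario record", {
  res <- start_session(1, "low", seed = 1)
  script <- c("ready", "s", "e", "t", "b", "done", "ok")
  st <- run_script(res$state, script)
  expect_identical(st$phase, "continue_prompt")
  out <- advance(st, "no")
  expect_identical(out$state$phase, "continue_prompt")
  expect_match(out$messages, "one more scenario")
  expect_identical(length(out$state$completed_records), 1L)
})

test_that("empty free-text input re-prompts without changing state", {
  res <- start_session(2, "low", seed = 4)
  st <- res$state
  out <- advance(st, "   ")
  expect_match(out$messages, "did not catch")
  expect_identical(out$state$transcript, st$transcript)
  expect_identical(out$state$phase, "ask_situation")
  # unknown button token also re-prompts
  res1 <- start_session(1, "low", seed = 4)
  out1 <- advance(res1$state, "banana")
  expect_identical(out1$state$phase, "scenario_presentation")
  expect_match(out1$messages, "ready")
})

test_that("downward arrow appends steps, re-probes, and respects the depth limit", {
  res <- start_session(2, "low", seed = 5)
  st <- run_script(res$state, c("s", "e", "t", "b"))
  expect_identical(st$phase, "downward_arrow")
  out <- downward_arrow_next(st, "it means i am unlovable")
  expect_identical(out$state$current$steps, "it means i am unlovable")
  expect_match(paste(out$messages, collapse = " "), "what would that mean")

  # stop after zero steps completes with an empty chain
  res0 <- start_session(2, "low", seed = 5)
  st0 <- run_script(res0$state, c("s", "e", "t", "b", "done"))
  expect_identical(st0$phase, "feedback")
  expect_length(st0$completed_records[[1]]$downward_steps, 0L)

  # depth limit forces termination: 26th input is not appended
  res2 <- start_session(2, "low", seed = 5)
  st2 <- run_script(res2$state,
                    c("s", "e", "t", "b", paste("step", 1:26)))
  expect_identical(st2$phase, "feedback")
  expect_length(st2$completed_records[[1]]$downward_steps, 25L)
})

test_that("identical seed and script replay byte-identically", {
  p <- persona_config(schema_profile = c(0, 1, rep(0, 7)))
  for (sess in 1:2) {
    script <- generate_transcript_script(p, sess, n_records = 2, seed = 17)
    s1 <- run_script(start_session(sess, "medium", seed = 23)$state, script)
    s2 <- run_script(start_session(sess, "medium", seed = 23)$state, script)
    expect_identical(transcript_to_jsonl(s1), transcript_to_jsonl(s2))
  }
})

test_that("completed sessions satisfy the record-count and origin invariants", {
  set.seed(31)
  for (i in 1:10) {
    persona <- persona_config(schema_profile = runif(9),
                              chain_depth_distribution = sample(0:4, 1),
                              stop_behavior = runif(1, 0, 0.3))
    cond <- sample(c("low", "medium", "high"), 1)
    n_rec <- sample(1:3, 1)
    s1 <- complete_session(1, cond, persona, seed = i)
    expect_identical(s1$phase, "closing")
    expect_length(s1$completed_records, 2L)
    expect_true(all(vapply(s1$completed_records, `[[`, "", "origin") ==
                      "scenario"))
    s2 <- complete_session(2, cond, persona, seed = 100 + i,
                           n_records = n_rec)
    expect_identical(s2$phase, "closing")
    expect_length(s2$completed_records, n_rec)
    expect_true(all(vapply(s2$completed_records, `[[`, "", "origin") ==
                      "personal"))
  }
})

test_that("feedback shown in-session never exceeds the condition's richness", {
  p <- persona_config()
  for (cond in c("low", "medium", "high")) {
    st <- complete_session(2, cond, p, seed = 71)
    fb <- st$last_feedback
    expect_identical(fb$richness, cond)
    if (cond == "low") {
      expect_null(fb$step_chart)
      expect_null(fb$spider)
    }
    if (cond == "medium") {
      expect_false(is.null(fb$step_chart))
      expect_null(fb$spider)
    }
    if (cond == "high") {
      expect_false(is.null(fb$step_chart))
      expect_false(is.null(fb$spider))
    }
  }
})

test_that("scenario YAML files load and match the built-in library", {
  path <- system.file("extdata", "scenarios.yaml", package = "thoughtrec")
  lib <- read_scenarios(path)
  expect_identical(lib, default_scenario_library())
})
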