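test_that("ordinal-to-binomial recode collapses any positive presence code", {
  expect_identical(recode_ordinal_to_binomial(0L), 0L)
  expect_identical(recode_ordinal_to_binomial(1L), 1L)
  expect_identical(recode_ordinal_to_binomial(2L), 1L)
  expect_identical(recode_ordinal_to_binomial(3L), 1L)
  expect_identical(recode_ordinal_to_binomial(c(0, 3, 1)), c(0L, 1L, 1L))
  # idempotent on its own output
  codes <- 0:3
  once <- recode_ordinal_to_binomial(codes)
  expect_identical(recode_ordinal_to_binomial(once), once)
  expect_error(recode_ordinal_to_binomial(4), "0, 1, 2, 3")
  expect_error(recode_ordinal_to_binomial(-1), "0, 1, 2, 3")
})

test_that("schema frequency distribution counts binomial presence per utterance", {
  m0 <- matrix(0L, 1L, 9L)
  expect_equal(schema_frequency_distribution(m0), rep(0, 9))

  m <- matrix(0L, 2L, 9L)
  m[1L, 1L] <- 1L
  expect_equal(schema_frequency_distribution(m), c(0.5, rep(0, 8)))

  m_all <- matrix(sample(1:3, 45, replace = TRUE), 5L, 9L)
  expect_equal(schema_frequency_distribution(m_all), rep(1, 9))

  expect_error(schema_frequency_distribution(matrix(integer(), 0L, 9L)),
               "zero utterances")

  # works on schema_activation lists and is invariant to utterance order
  set.seed(11)
  mm <- matrix(sample(0:3, 90, replace = TRUE), 10L, 9L)
  acts <- activations_from_ordinal(mm)
  f1 <- schema_frequency_distribution(acts)
  for (rep in 1:5) {
    perm <- sample(length(acts))
    expect_equal(schema_frequency_distribution(acts[perm]), f1)
  }
  expect_equal(f1, colMeans(mm != 0))
})

test_that("rank correlation matches closed-form Spearman and flags constants", {
  a <- as.numeric(1:9) / 10
  expect_equal(rank_correlation(a, a), 1)
  expect_equal(rank_correlation(a, rev(a)), -1)
  b <- c(1:7, 9, 8) / 10
  # one adjacent swap: rho = 1 - 6*2/(9*80) = 59/60
  expect_equal(rank_correlation(a, b), 59 / 60)
  expect_warning(r <- rank_correlation(rep(0.5, 9), a), "undefined")
  expect_true(is.na(r))
})

test_that("record serialization round-trips through CSV and JSON Lines", {
  recs <- list(
    thought_record("r1", "p1", 1, "scenario", scenario_id = "int1",
                   situation = "a friend cancelled, again",
                   emotion = "sad", automatic_thought = "nobody likes me",
                   behavior = "went home",
                   downward_steps = c("i am unlovable", "i will end up alone",
                                      "being alone means i am worthless"),
                   created_at = 12L),
    thought_record("r2", "p1", 2, "personal",
                   situation = "argument with my boss, with a \"quote\"",
                   emotion = "angry", automatic_thought = "i always fail",
                   behavior = "said nothing", created_at = 30L)
  )
  for (ext in c("csv", "jsonl")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_records(recs, path)
    back <- read_records(path)
    expect_length(back, 2L)
    for (i in 1:2) expect_equal(unclass(back[[i]]), unclass(recs[[i]]),
                                info = ext)
    unlink(path)
  }
  # empty set round-trips
  p <- tempfile(fileext = ".csv")
  write_records(list(), p)
  expect_length(read_records(p), 0L)
  unlink(p)
})

test_that("serialization round-trip is the identity on random record sets", {
  set.seed(202)
  words <- c("alone", "fail", "worthless", "sick", "ok", "thought")
  rand_text <- function() paste(sample(words, sample(2:5, 1), TRUE),
                                collapse = " ")
  for (case in 1:10) {
    n <- sample(1:4, 1)
    recs <- lapply(seq_len(n), function(i) {
      sess <- sample(1:2, 1)
      thought_record(
        paste0("r", i), "px", sess,
        if (sess == 1) "scenario" else "personal",
        scenario_id = if (sess == 1) "ach2" else NULL,
        situation = rand_text(), emotion = rand_text(),
        automatic_thought = rand_text(), behavior = rand_text(),
        downward_steps = replicate(sample(0:6, 1), rand_text()),
        created_at = i)
    })
    path <- tempfile(fileext = sample(c(".csv", ".jsonl"), 1))
    write_records(recs, path)
    back <- read_records(path)
    expect_equal(lapply(back, unclass), lapply(recs, unclass))
    unlink(path)
  }
})

test_that("malformed record files and invalid records are rejected", {
  # missing emotion -> parse error naming the record
  path <- tempfile(fileext = ".csv")
  df <- data.frame(record_id = "bad1", participant_id = "p", session_index = 2,
                   origin = "personal", scenario_id = "", situation = "s",
                   emotion = "", automatic_thought = "t", behavior = "b",
                   n_steps = 0, created_at = 1)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_records(path), "bad1")
  unlink(path)

  expect_error(thought_record("r", "p", 1, "personal", "s", "e", "t", "b"),
               "origin")
  expect_error(thought_record("r", "p", 2, "scenario", "s", "e", "t", "b",
                              scenario_id = "x"), "origin|personal")
  expect_error(thought_record("r", "p", 1, "scenario", "s", "e", "t", "b"),
               "scenario_id")
})

test_that("schema_activation enforces consistency with the threshold map", {
  a <- schema_activation("u1", c(0, 0.3, 0.6, 0.9, rep(0, 5)))
  expect_identical(a$ordinal_codes, c(0L, 1L, 2L, 3L, rep(0L, 5)))
  expect_error(schema_activation("u1", rep(0.9, 9), ordinal_codes = rep(1L, 9)),
               "inconsistent")
  expect_error(schema_activation("u1", rep(1.2, 9)), "\\[0, 1\\]")
})
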