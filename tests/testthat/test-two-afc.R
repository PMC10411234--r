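test_that("study config validates passcode, pairs and files", {
  cfg <- tiny_config()
  expect_identical(cfg$passcode, "1234")
  expect_error(study_config("t", "12a4", cfg$pairs), "4 digits")
  expect_error(study_config("t", "12345", cfg$pairs), "4 digits")
  expect_error(study_config("t", "1234", cfg$pairs[0, ]), "non-empty")
  expect_error(
    study_config("t", "1234",
                 data.frame(synthetic = "nope.png", real = "nah.png")),
    "not found")
})

test_that("sessions are deterministic, complete and side-balanced", {
  cfg <- tiny_config(n = 50L, shuffle = TRUE, shuffle_seed = 17L)
  s1 <- build_session(cfg)
  s2 <- build_session(cfg)
  expect_identical(s1, s2)
  expect_identical(s1$trial_id, 1:50)
  expect_setequal(s1$synthetic_ref, cfg$pairs$synthetic)
  # shuffle off preserves upload order
  cfg0 <- tiny_config(n = 6L, shuffle = FALSE)
  s0 <- build_session(cfg0)
  expect_identical(s0$synthetic_ref, cfg0$pairs$synthetic)
  # seeded fair coin: binomial 3-sigma band around 25 of 50
  expect_lt(abs(sum(s1$left_is_real) - 25), 3 * sqrt(50 * 0.25))
})

test_that("session files round-trip through JSON", {
  cfg <- tiny_config(n = 5L, shuffle = TRUE, shuffle_seed = 3L)
  ses <- build_session(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_session(cfg, ses, f)
  back <- read_session(f)
  expect_equal(as.data.frame(back$session), as.data.frame(ses))
  expect_equal(back$config$passcode, cfg$passcode)
  expect_identical(build_session(back$config), ses)
})

test_that("scoring derives correctness, medians and exact binomial inference", {
  cfg <- tiny_config(n = 4L)
  ses <- build_session(cfg)
  log <- data.frame(
    reader_id = "r1", trial_id = 1:4,
    chosen_side = ifelse(c(ses$left_is_real[1:2], !ses$left_is_real[3:4]),
                         "left", "right"),
    confidence = c(2L, 2L, 4L, 4L), comment = "",
    stringsAsFactors = FALSE)
  s <- score_responses(ses, log, "r1")
  expect_equal(s$n_correct, 2L)
  expect_equal(s$percent_accuracy, 50)
  # lower-median convention on {2,2,4,4}
  expect_identical(s$median_confidence, 2L)
  bt <- binom.test(2, 4, 0.5)
  expect_equal(s$binomial_p_vs_chance, bt$p.value)
  expect_equal(s$ci95, as.numeric(bt$conf.int))
  expect_equal(sum(s$confidence_tally), 4L)
  # extreme case: all wrong
  log$chosen_side <- ifelse(ses$left_is_real, "right", "left")
  s0 <- score_responses(ses, log, "r1")
  expect_equal(s0$percent_accuracy, 0)
  # n = 4 is too small for the Clopper-Pearson upper bound to drop
  # below 1/2; the below-chance flag is exercised at n = 50 below
  big_wrong <- data.frame(
    reader_id = "r2", trial_id = rep(1:4, 13)[1:50], chosen_side = "left",
    confidence = 1L, comment = "")
  expect_error(score_responses(ses, big_wrong, "r2"), "duplicate")
  bad_trial <- data.frame(reader_id = "r3", trial_id = 99L,
                          chosen_side = "left", confidence = 1L,
                          comment = "")
  expect_error(score_responses(ses, bad_trial, "r3"), "unknown trial")
})

test_that("fifty-trial binomial extreme gives a vanishing p-value", {
  tally <- matrix(0L, 2, 5, dimnames = list(c("correct", "incorrect"), 1:5))
  tally["incorrect", 1] <- 50L
  s <- realismeval:::new_reader_summary("r", tally)
  expect_equal(s$percent_accuracy, 0)
  expect_lt(s$binomial_p_vs_chance, 1e-12)
  expect_true(s$untrained_flag)
})

test_that("pooling conserves counts and is identity for one reader", {
  fx <- paper_worked_example()
  sums <- lapply(fx$pooled_logs, function(lg) {
    score_responses(fx$session, lg, lg$reader_id[1])
  })
  pooled <- pooled_summary(sums)
  expect_equal(pooled$n_trials, sum(vapply(sums, `[[`, 0L, "n_trials")))
  expect_equal(pooled$n_correct, sum(vapply(sums, `[[`, 0L, "n_correct")))
  expect_equal(sum(pooled$confidence_tally["correct", ]),
               pooled$n_correct)
  expect_equal(sum(pooled$confidence_tally), pooled$n_trials)
  one <- pooled_summary(list(sums[[1]]))
  expect_equal(one$n_correct, sums[[1]]$n_correct)
  expect_equal(one$confidence_tally, sums[[1]]$confidence_tally)
  # permutation invariance of log row order
  shuf <- fx$pooled_logs[[1]][sample(50), ]
  expect_equal(score_responses(fx$session, shuf, shuf$reader_id[1])$confidence_tally,
               sums[[1]]$confidence_tally)
})

test_that("confidence_fraction counts thresholds and rejects empty strata", {
  fx <- paper_worked_example()
  sums <- lapply(fx$pooled_logs, function(lg) {
    score_responses(fx$session, lg, lg$reader_id[1])
  })
  pooled <- pooled_summary(sums)
  all_corr <- confidence_fraction(pooled, TRUE, 1)
  expect_equal(all_corr$count, pooled$n_correct)
  expect_equal(all_corr$percent, 100)
  tally <- matrix(0L, 2, 5, dimnames = list(c("correct", "incorrect"), 1:5))
  tally["correct", 3] <- 10L
  s <- realismeval:::new_reader_summary("r", tally)
  expect_error(confidence_fraction(s, FALSE, 4), "undefined")
  expect_error(confidence_fraction(pooled, TRUE, 0), "1..5")
})

test_that("response logs round-trip through CSV with comments quoted", {
  cfg <- tiny_config(n = 3L)
  ses <- build_session(cfg)
  log <- data.frame(
    reader_id = "dr, who", trial_id = 1:3, chosen_side = "left",
    confidence = c(1L, 5L, 3L),
    comment = c("too smooth, maybe", "", "odd \"texture\""),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_response_log(log, f)
  back <- read_response_log(f)
  expect_equal(back, realismeval:::validate_response_log(log))
  expect_error(read_response_log({
    bad <- log; bad$confidence[1] <- 9L
    f2 <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(bad, f2, row.names = FALSE); f2
  }), "1..5")
})

test_that("SUS scoring follows the alternating rule and its symmetries", {
  best <- rep(c("strongly agree", "strongly disagree"), 5)
  worst <- rep(c("strongly disagree", "strongly agree"), 5)
  expect_identical(sus_score(best), 100)
  expect_identical(sus_score(worst), 0)
  expect_identical(sus_score(rep("neutral", 10)), 50)
  # flip symmetry and monotonicity on random questionnaires
  withr::with_seed(99, {
    for (i in 1:40) {
      resp <- sample(sus_labels, 10, replace = TRUE)
      flipped <- sus_labels[6 - match(resp, sus_labels)]
      expect_identical(sus_score(resp) + sus_score(flipped), 100)
      item <- sample(10, 1)
      lvl <- match(resp[item], sus_labels)
      better <- resp
      # more favorable = more agreement on odd items, less on even
      if (item %% 2 == 1 && lvl < 5) better[item] <- sus_labels[lvl + 1]
      if (item %% 2 == 0 && lvl > 1) better[item] <- sus_labels[lvl - 1]
      expect_gte(sus_score(better), sus_score(resp))
    }
  })
  expect_error(sus_score(rep("neutral", 9)), "10 item")
  expect_error(sus_score(c(rep("neutral", 9), "meh")), "invalid")
})

test_that("SUS response files are read and scored per respondent", {
  df <- as.data.frame(matrix("neutral", 3, 10,
                             dimnames = list(NULL, paste0("item", 1:10))))
  df[2, ] <- rep(c("strongly agree", "strongly disagree"), 5)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  scored <- read_sus_responses(f)
  expect_equal(scored$score, c(50, 100, 50))
})
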