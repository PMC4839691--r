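test_that("template decisions follow the signed decision variable", {
  tmpl <- matrix(0, 4, 5)
  tmpl[2, 2] <- 1
  coch <- matrix(0, 4, 5)
  coch[2, 2] <- 2
  # noiseless: d > 0 deterministically
  obs <- template_observer(tmpl, criterion = 1, internal_noise_sd = 0)
  expect_identical(decide(obs, coch), 1L)
  obs2 <- template_observer(tmpl, criterion = 3, internal_noise_sd = 0)
  expect_identical(decide(obs2, coch), 0L)
  expect_error(decide(obs, matrix(0, 3, 5)), "shape")
  # zero template, noisy criterion: responses are a fair coin
  obs3 <- template_observer(matrix(0, 4, 5), criterion = 0,
                            internal_noise_sd = 1)
  r <- withr::with_seed(1, replicate(10000, decide(obs3, coch)))
  expect_lt(abs(mean(r) - 0.5), 3 * sqrt(0.25 / 10000) + 0.005)
})

test_that("the ideal observer is nearly perfect at high SNR", {
  tg <- fix_targets()
  fb <- fix_small_fb()
  obs <- fix_small_observer()
  correct <- withr::with_seed(11, {
    sapply(1:200, function(i) {
      ti <- (i %% 4) + 1
      mix <- mix_at_snr(tg$waveforms[, ti], generate_noise(5000 + i), 20)
      r <- decide(obs, cochleogram(mix, fb, n_frames = 20))
      r == as.integer(tg$classes$stop_class[ti] == "ga")
    })
  })
  expect_gt(mean(correct), 0.95)
})

test_that("3-down 1-up updates implement Levitt's rule", {
  st <- staircase_state(start_snr_db = 0, step_db = 2, final_step_db = 1)
  # an error raises SNR by one step and resets the counter
  s1 <- staircase_update(st, FALSE)
  expect_equal(s1$current_snr, 2)
  expect_equal(s1$consecutive_correct, 0L)
  # two corrects only count
  s2 <- staircase_update(staircase_update(st, TRUE), TRUE)
  expect_equal(s2$current_snr, 0)
  expect_equal(s2$consecutive_correct, 2L)
  # the third consecutive correct lowers SNR and resets
  s3 <- staircase_update(s2, TRUE)
  expect_equal(s3$current_snr, -2)
  expect_equal(s3$consecutive_correct, 0L)
  # counter stays in 0..2 and step drops to 1 dB after the first reversal
  s4 <- staircase_update(s3, FALSE)
  expect_equal(s4$step_db, 1)
  expect_equal(s4$current_snr, -2 + 2)  # reversal applied pre-switch step
})

test_that("an always-correct observer marches to the SNR floor", {
  st <- staircase_state(start_snr_db = 0, step_db = 2, final_step_db = 2,
                        floor_snr_db = -10)
  snrs <- numeric(60)
  for (i in 1:60) {
    snrs[i] <- st$current_snr
    st <- staircase_update(st, TRUE)
  }
  expect_true(all(diff(snrs) <= 0))
  expect_equal(st$current_snr, -10)
})

test_that("experiments are reproducible and correctly structured", {
  obs <- psychometric_observer(midpoint_db = -12, slope = 1)
  tg <- fix_targets()
  t1 <- run_experiment(obs, tg, n_trials = 1000, trials_per_session = 500,
                       seed = 4)
  t2 <- run_experiment(obs, tg, n_trials = 1000, trials_per_session = 500,
                       seed = 4)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 1000)
  expect_equal(unique(table(t1$session)), 500, ignore_attr = TRUE)
  expect_setequal(unique(t1$target), tg$labels)
  # correctness coding: r=1 on 'ga' words or r=0 on 'da' words
  is_ga <- grepl("ga$", t1$target)
  expect_equal(t1$correct,
               (t1$response == 1) == is_ga)
  expect_error(run_experiment(obs, tg, n_trials = 1001,
                              trials_per_session = 500),
               "divisible")
})

test_that("percent correct at fixed SNR is monotone in SNR", {
  obs <- psychometric_observer(midpoint_db = -12, slope = 1)
  tg <- fix_targets()
  pc <- sapply(c(-20, -14, -10, -6), function(snr) {
    tr <- run_experiment(obs, tg, n_trials = 1000,
                         trials_per_session = 1000, seed = 8,
                         staircase = staircase_state(
                           start_snr_db = snr, step_db = 0,
                           final_step_db = 0, floor_snr_db = snr,
                           ceiling_snr_db = snr))
    mean(tr$correct)
  })
  expect_true(all(diff(pc) > -0.04))  # binomial noise allowance
  expect_gt(pc[4], pc[1])
})

test_that("performance summaries give textbook d-prime values", {
  expect_equal(dprime(0.9, 0.1), 2 * qnorm(0.9), tolerance = 1e-10)
  expect_equal(round(dprime(0.9, 0.1), 4), 2.5631)
  expect_equal(dprime(0.3, 0.3), 0)
  # summary on a constructed table: 9/10 hits, 1/10 false alarms
  tr <- tibble::tibble(
    trial = 1:20, session = 1L,
    target = rep(c("alga", "alda"), each = 10),
    noise_seed = 1:20, snr_db = 0,
    response = c(rep(1L, 9), 0L, rep(0L, 9), 1L),
    correct = c(rep(TRUE, 9), FALSE, rep(TRUE, 9), FALSE)
  )
  ps <- performance_summary(tr)
  expect_equal(ps$percent_correct, 90)
  expect_equal(ps$hit_rate, 0.9)
  expect_equal(ps$fa_rate, 0.1)
  expect_equal(ps$dprime, 2 * qnorm(0.9))
  expect_error(performance_summary(tr[0, ]), "empty")
})

test_that("predictors collected during the run match recomputation", {
  tg <- fix_targets()
  fb <- fix_small_fb()
  tr <- run_experiment(fix_small_observer(), tg, n_trials = 30,
                       trials_per_session = 30, seed = 17,
                       filterbank = fb, n_frames = 20,
                       keep_predictors = TRUE)
  inline <- attr(tr, "predictors")
  recomputed <- trial_predictors(tr, tg, fb, n_frames = 20)
  expect_equal(unclass(inline), unclass(recomputed), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(run_experiment(psychometric_observer(), tg, n_trials = 30,
                              trials_per_session = 30,
                              keep_predictors = TRUE),
               "template")
})

test_that("trial tables round-trip through CSV without loss", {
  sim <- fix_small_experiment()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(sim$trials, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$trials))
})
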