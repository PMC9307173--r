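fake_features <- function(n, delta = 1, theta = 1, emg = 10) {
  data.frame(delta_power = rep(delta, n), theta_power = rep(theta, n),
             fast_power = 1, emg_rms = rep(emg, n),
             emg_rms_median = rep(emg, n), bin_5 = 0)
}

test_that("calibration returns the EMG quantile and scales with the channel", {
  f <- fake_features(40, emg = 10)
  cal <- calibrate(f)
  expect_equal(cal$wake_emg_ref, 10)
  f2 <- f; f2$emg_rms <- f2$emg_rms * 2; f2$emg_rms_median <- f2$emg_rms_median * 2
  expect_equal(calibrate(f2)$wake_emg_ref, 20)
  expect_error(calibrate(fake_features(10)), "at least 30")
})

test_that("calibration recovers the configured wake EMG level", {
  b <- battery_recording(1)
  cal <- calibrate(epoch_features(b$recording, 20))
  expect_lt(abs(cal$wake_emg_ref - b$config$emg_level[["wake"]]),
            0.25 * b$config$emg_level[["wake"]])
})

test_that("epoch classification follows the three stage criteria", {
  cal <- list(wake_emg_ref = 100)
  th <- staging_thresholds()
  expect_equal(classify_epoch(fake_features(1, delta = 4, theta = 1, emg = 10),
                              th, cal), "NREM")
  expect_equal(classify_epoch(fake_features(1, delta = 1, theta = 3, emg = 2),
                              th, cal), "REM")
  expect_equal(classify_epoch(fake_features(1, delta = 1, theta = 1, emg = 100),
                              th, cal), "Wake")
  # atonia + theta dominance wins over the NREM test (decision order)
  expect_equal(classify_epoch(fake_features(1, delta = 3, theta = 6, emg = 2),
                              th, cal), "REM")
  # total function: every epoch gets some label
  set.seed(1)
  f <- fake_features(50, delta = runif(50, 0.1, 5), theta = runif(50, 0.1, 5),
                     emg = runif(50, 1, 120))
  f$delta_power <- runif(50, 0.1, 5); f$theta_power <- runif(50, 0.1, 5)
  lab <- classify_epoch(f, th, cal)
  expect_true(all(lab %in% c("Wake", "NREM", "REM")))
  expect_identical(lab, classify_epoch(f, th, cal))
})

test_that("scored hypnograms recover ground-truth predominant labels", {
  for (s in battery_seeds) {
    sc <- battery_scored(s)
    expect_gte(mean(sc$hyp20$labels == sc$gt20$labels), 0.90)
  }
})

test_that("an all-wake recording scores all wake", {
  cfg <- sim_config(duration = 660, sampling_rate = 100,
                    mean_bout = c(Wake = Inf, NREM = 100, REM = 70))
  tr <- simulate_states(cfg, 4)
  rec <- synthesize_signals(tr, cfg, 4)
  hyp <- score_recording(rec, 20)
  expect_true(all(hyp$labels == "Wake"))
})

test_that("4-s scoring majority-pooled per 20-s block matches 20-s scoring", {
  for (s in battery_seeds) {
    sc <- battery_scored(s)
    pooled <- pool_hypnogram(sc$hyp4, 20)
    n <- min(length(pooled$labels), length(sc$hyp20$labels))
    expect_gte(mean(pooled$labels[1:n] == sc$hyp20$labels[1:n]), 0.85)
  }
})

test_that("the predominant-state rule and its tie-breaks are honored", {
  expect_equal(predominant_label(rep(c("Wake", "NREM"), c(12, 8))), "Wake")
  expect_equal(predominant_label(rep("NREM", 20)), "NREM")
  expect_equal(predominant_label(rep(c("Wake", "NREM"), c(10, 10)),
                                 prev = "NREM"), "NREM")
  expect_equal(predominant_label(rep(c("Wake", "NREM"), c(10, 10)),
                                 prev = "REM"), "Wake")
  expect_equal(predominant_label(rep(c("NREM", "REM"), c(10, 10))), "NREM")
  expect_error(predominant_label(character(0)), "empty")
})

test_that("20-s scoring lengthens episodes and reduces transitions vs 4-s", {
  per_state_20 <- matrix(0, 0, 3); per_state_4 <- matrix(0, 0, 3)
  for (s in battery_seeds) {
    sc <- battery_scored(s)
    s20 <- summarize_architecture(sc$hyp20)
    s4 <- summarize_architecture(sc$hyp4)
    # the claim's own quantities, per recording
    expect_gte(s20$mean_episode_duration_s[["Wake"]],
               s4$mean_episode_duration_s[["Wake"]])
    expect_lte(sum(s20$transition_counts), sum(s4$transition_counts))
    overall20 <- sum(s20$total_s) / sum(s20$n_episodes)
    overall4 <- sum(s4$total_s) / sum(s4$n_episodes)
    expect_gte(overall20, overall4)
    per_state_20 <- rbind(per_state_20, s20$mean_episode_duration_s)
    per_state_4 <- rbind(per_state_4, s4$mean_episode_duration_s)
  }
  # per state the effect is systematic across the battery
  expect_true(all(colMeans(per_state_20, na.rm = TRUE) >=
                    colMeans(per_state_4, na.rm = TRUE)))
})

test_that("drug-effect signs agree between 20-s and 4-s scoring", {
  d20 <- c(); d4 <- c(); t20 <- c(); t4 <- c()
  for (s in battery_seeds) {
    v <- battery_scored(s, "vehicle"); d <- battery_scored(s, "drug")
    sv20 <- summarize_architecture(v$hyp20); sd20 <- summarize_architecture(d$hyp20)
    sv4 <- summarize_architecture(v$hyp4); sd4 <- summarize_architecture(d$hyp4)
    d20 <- c(d20, sd20$total_s[["Wake"]] - sv20$total_s[["Wake"]])
    d4 <- c(d4, sd4$total_s[["Wake"]] - sv4$total_s[["Wake"]])
    wn <- function(x) x$transition_counts[["W>N"]] + x$transition_counts[["N>W"]]
    t20 <- c(t20, wn(sd20) - wn(sv20))
    t4 <- c(t4, wn(sd4) - wn(sv4))
  }
  expect_gt(mean(d20), 0)
  expect_equal(sign(mean(d20)), sign(mean(d4)))
  expect_lt(mean(t20), 0)
  expect_equal(sign(mean(t20)), sign(mean(t4)))
})
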