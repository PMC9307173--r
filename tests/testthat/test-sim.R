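test_that("a forced single-state chain emits only that state", {
  cfg <- sim_config(duration = 600,
                    mean_bout = c(Wake = Inf, NREM = 100, REM = 70))
  tr <- simulate_states(cfg, 1)
  expect_length(tr$labels, 600)
  expect_true(all(tr$labels == "Wake"))
})

test_that("state simulation is reproducible for a fixed seed", {
  cfg <- sim_config(duration = 3600)
  expect_identical(simulate_states(cfg, 7)$labels,
                   simulate_states(cfg, 7)$labels)
  expect_false(identical(simulate_states(cfg, 7)$labels,
                         simulate_states(cfg, 8)$labels))
})

test_that("empirical wake bout durations match the configured mean", {
  cfg <- sim_config(duration = battery_duration)
  tr <- simulate_states(cfg, 1)
  runs <- scan_runs(tr$labels)
  # interior wake bouts not truncated by cataplexy onset or recording edges
  wake <- runs[runs$state == "Wake", ]
  follows_cat <- c(FALSE, runs$state[-nrow(runs)] == "Cataplexy")[runs$state == "Wake"]
  precedes_cat <- c(runs$state[-1] == "Cataplexy", FALSE)[runs$state == "Wake"]
  clean <- wake[!follows_cat & !precedes_cat, ]
  expect_gt(nrow(clean), 20)
  expect_lt(abs(mean(clean$len) - cfg$mean_bout[["Wake"]]),
            0.15 * cfg$mean_bout[["Wake"]])
})

test_that("bout-duration sample means sit within 3 standard errors", {
  cfg <- sim_config(duration = 24 * 3600, cataplexy_hazard = 0)
  runs <- rbind(scan_runs(simulate_states(cfg, 3)$labels),
                scan_runs(simulate_states(cfg, 13)$labels))
  for (s in c("Wake", "NREM", "REM")) {
    len <- runs$len[runs$state == s]
    len <- len[-c(1, length(len))]  # drop edge-truncated bouts
    expect_gt(length(len), 100)
    se <- sd(len) / sqrt(length(len))
    expect_lt(abs(mean(len) - cfg$mean_bout[[s]]), 3 * se)
  }
})

test_that("REM is never entered directly from Wake", {
  for (s in battery_seeds) {
    lab <- battery_recording(s)$track$labels
    a <- lab[-length(lab)]; b <- lab[-1]
    expect_equal(sum(a == "Wake" & b == "REM"), 0)
  }
})

test_that("drug effect scales only the wake bout mean and hazard", {
  cfg <- sim_config()
  same <- apply_drug_effect(cfg, 1, 1)
  expect_equal(unclass(same), unclass(cfg))
  d <- apply_drug_effect(cfg, 3, 0.2)
  expect_equal(d$mean_bout[["Wake"]], 3 * cfg$mean_bout[["Wake"]])
  expect_equal(d$cataplexy_hazard, 0.2 * cfg$cataplexy_hazard)
  expect_equal(d$mean_bout[["NREM"]], cfg$mean_bout[["NREM"]])
  expect_error(apply_drug_effect(cfg, 0, 1), "positive")
})

test_that("longer wake bouts monotonically reduce wake/NREM transitions", {
  cfg <- sim_config(duration = battery_duration)
  wn_trans <- function(lab) {
    a <- lab[-length(lab)]; b <- lab[-1]
    sum((a == "Wake" & b == "NREM") | (a == "NREM" & b == "Wake"))
  }
  means <- sapply(c(1, 2, 4), function(m) {
    cfg_m <- apply_drug_effect(cfg, m, 1)
    mean(sapply(1:10, function(s) wn_trans(simulate_states(cfg_m, s)$labels)))
  })
  expect_true(all(diff(means) < 0))
})

test_that("drug config lowers transition and cataplexy counts over seeds", {
  cfg <- sim_config(duration = battery_duration)
  drug <- apply_drug_effect(cfg, 3, 0.2)
  wn <- function(lab) {
    a <- lab[-length(lab)]; b <- lab[-1]
    sum((a == "Wake" & b == "NREM") | (a == "NREM" & b == "Wake"))
  }
  tv <- sapply(1:10, function(s) {
    tr <- simulate_states(cfg, s)
    c(wn(tr$labels), nrow(tr$ground_truth_events))
  })
  td <- sapply(1:10, function(s) {
    tr <- simulate_states(drug, s)
    c(wn(tr$labels), nrow(tr$ground_truth_events))
  })
  expect_lt(mean(td[1, ]), mean(tv[1, ]))
  expect_lt(mean(td[2, ]), mean(tv[2, ]))
})

test_that("signal synthesis is deterministic and state-conditioned", {
  cfg <- sim_config(duration = 120, sampling_rate = 100)
  tr <- simulate_states(cfg, 2)
  r1 <- synthesize_signals(tr, cfg, 5)
  r2 <- synthesize_signals(tr, cfg, 5)
  expect_identical(r1$eeg, r2$eeg)
  expect_identical(r1$emg, r2$emg)
  expect_length(r1$eeg, 120 * 100)

  nrem <- synthesize_signals(state_track(rep("NREM", 120)), cfg, 6)
  f <- epoch_features(nrem, 20)
  expect_true(all(f$delta_power > f$theta_power))
  expect_true(all(f$delta_power > f$fast_power))

  rem <- synthesize_signals(state_track(rep("REM", 120)), cfg, 7)
  emg_rms <- sqrt(mean(rem$emg^2))
  expect_lt(emg_rms, 0.5 * cfg$emg_level[["nrem"]])
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(duration = -5), "duration")
  expect_error(sim_config(emg_level = c(wake = 5, nrem = 10, atonia = 2)),
               "atonia < nrem < wake")
  bw <- default_band_weights(); bw[1, 1] <- 0.9
  expect_error(sim_config(band_weights = bw), "sum to 1")
  expect_error(sim_config(mean_bout = c(Wake = -1, NREM = 100, REM = 70)),
               "positive")
})
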