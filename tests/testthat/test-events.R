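test_that("the three criteria select exactly the qualifying episode", {
  p <- cataplexy_params()
  wake <- c(rep(TRUE, 60), rep(FALSE, 20), rep(TRUE, 20))
  qual <- c(rep(FALSE, 60), rep(TRUE, 20), rep(FALSE, 20))
  ev <- detect_cataplexy(wake, qual, qual, p)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 60)
  expect_equal(ev$duration_s, 20)
  expect_equal(ev$prior_wake_s, 60)

  # criterion (i): atonia shorter than 10 s
  wake8 <- c(rep(TRUE, 60), rep(FALSE, 8), rep(TRUE, 20))
  qual8 <- c(rep(FALSE, 60), rep(TRUE, 8), rep(FALSE, 20))
  expect_equal(nrow(detect_cataplexy(wake8, qual8, qual8, p)), 0)

  # criterion (iii): only 30 s of preceding wake
  wake30 <- c(rep(TRUE, 30), rep(FALSE, 20), rep(TRUE, 20))
  qual30 <- c(rep(FALSE, 30), rep(TRUE, 20), rep(FALSE, 20))
  expect_equal(nrow(detect_cataplexy(wake30, qual30, qual30, p)), 0)

  expect_error(detect_cataplexy(wake, qual[-1], qual, p), "equal length")
})

test_that("sub-merge-gap interruptions are bridged before the criteria", {
  p <- cataplexy_params()
  wake <- c(rep(TRUE, 50), rep(FALSE, 15), rep(TRUE, 10))
  qual <- c(rep(FALSE, 50), rep(TRUE, 7), FALSE, rep(TRUE, 7), rep(FALSE, 10))
  ev <- detect_cataplexy(wake, qual, qual, p)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 15)
})

test_that("detector output equals the brute-force enumerator on random tracks", {
  set.seed(20240901)
  p <- cataplexy_params()
  n_events <- 0
  for (i in 1:1000) {
    wake <- markov_flags(600, stay = 0.97, start = TRUE)
    atonia <- markov_flags(600, stay = 0.95)
    theta <- markov_flags(600, stay = 0.90)
    got <- detect_cataplexy(wake, atonia, theta, p)
    want <- brute_force_cataplexy(wake, atonia, theta, p)
    expect_identical(got, want)
    n_events <- n_events + nrow(got)
  }
  expect_gt(n_events, 50)  # the random battery actually exercises events
})

test_that("every emitted event satisfies all three criteria post hoc", {
  set.seed(7)
  p <- cataplexy_params()
  for (i in 1:50) {
    wake <- markov_flags(600, stay = 0.97, start = TRUE)
    atonia <- markov_flags(600, stay = 0.95)
    theta <- markov_flags(600, stay = 0.90)
    ev <- detect_cataplexy(wake, atonia, theta, p)
    if (nrow(ev) == 0) next
    expect_true(all(ev$duration_s >= p$min_atonia_s))
    expect_true(all(ev$prior_wake_s >= p$min_prior_wake_s))
  }
})

test_that("detector recall and precision reach 0.9 on the synthetic battery", {
  tp <- 0; fn <- 0; fp <- 0; decoys_seen <- 0; decoys_rejected <- 0
  for (s in battery_seeds) {
    b <- battery_recording(s)
    ev <- battery_scored(s)$events
    g <- b$track$ground_truth_events
    true_ev <- g[g$prior_wake_s >= 40, ]
    decoy_ev <- g[g$prior_wake_s < 40, ]
    matched <- rep(FALSE, nrow(ev))
    for (i in seq_len(nrow(true_ev))) {
      hit <- which(!matched & abs(ev$onset_s - true_ev$onset_s[i]) <= 5)
      if (length(hit)) { tp <- tp + 1; matched[hit[1]] <- TRUE } else fn <- fn + 1
    }
    for (i in seq_len(nrow(decoy_ev))) {
      decoys_seen <- decoys_seen + 1
      near <- any(abs(ev$onset_s - decoy_ev$onset_s[i]) <= 5)
      if (!near) decoys_rejected <- decoys_rejected + 1
    }
    fp <- fp + sum(!matched)
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_gte(tp / (tp + fp), 0.9)
  expect_equal(decoys_rejected, decoys_seen)  # <40 s prior wake never passes
})

test_that("event counting and latency follow the censoring convention", {
  ev <- data.frame(onset_s = c(100, 5000), duration_s = c(20, 30),
                   prior_wake_s = c(60, 80))
  cl <- count_and_latency(ev, 10800)
  expect_equal(cl$count, 2)
  expect_equal(cl$latency_s, 100)
  none <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                     prior_wake_s = numeric(0))
  cl0 <- count_and_latency(none, 10800)
  expect_equal(cl0$count, 0)
  expect_equal(cl0$latency_s, 10800)
  # events past the window edge are excluded by onset
  cl1 <- count_and_latency(ev, 3000)
  expect_equal(cl1$count, 1)
})

test_that("suppressing the hazard lowers counts and lengthens latency", {
  counts_v <- c(); counts_d <- c(); lat_v <- c(); lat_d <- c()
  for (s in battery_seeds) {
    ev_v <- battery_scored(s, "vehicle")$events
    ev_d <- battery_scored(s, "drug")$events
    cv <- count_and_latency(ev_v, battery_duration)
    cd <- count_and_latency(ev_d, battery_duration)
    counts_v <- c(counts_v, cv$count); counts_d <- c(counts_d, cd$count)
    lat_v <- c(lat_v, cv$latency_s); lat_d <- c(lat_d, cd$latency_s)
  }
  expect_lt(mean(counts_d), mean(counts_v))
  expect_gt(mean(lat_d), mean(lat_v))
})
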