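# Shared synthetic battery: 6 seed-matched vehicle/drug recording pairs at
# the default OXKO dark-phase conditions, 3 h each, built once per test run.
# Signal seeds are offset from state seeds so the two RNG streams differ.

battery_seeds <- 1:6
battery_duration <- 3 * 3600

.battery_cache <- new.env(parent = emptyenv())

battery_recording <- function(seed, arm = c("vehicle", "drug")) {
  arm <- match.arg(arm)
  key <- paste0(arm, "_", seed)
  if (!is.null(.battery_cache[[key]])) return(.battery_cache[[key]])
  cfg <- sim_config(duration = battery_duration)
  if (arm == "drug") cfg <- apply_drug_effect(cfg, 3, 0.2)
  track <- simulate_states(cfg, seed)
  rec <- synthesize_signals(track, cfg, seed + 100)
  out <- list(config = cfg, track = track, recording = rec)
  .battery_cache[[key]] <- out
  out
}

battery_scored <- function(seed, arm = "vehicle") {
  key <- paste0("scored_", arm, "_", seed)
  if (!is.null(.battery_cache[[key]])) return(.battery_cache[[key]])
  b <- battery_recording(seed, arm)
  out <- list(
    hyp20 = score_recording(b$recording, 20),
    hyp4 = score_recording(b$recording, 4),
    gt20 = track_to_hypnogram(b$track, 20),
    events = detect_cataplexy_recording(b$recording)
  )
  .battery_cache[[key]] <- out
  out
}

# Independent brute-force cataplexy enumerator used as the detector oracle.
# Deliberately different algorithm: gap-closing by per-gap inspection, then
# run scanning, then a literal backwards prior-wake count.
brute_force_cataplexy <- function(wake, atonia, theta_dom, params) {
  n <- length(wake)
  qual <- atonia & theta_dom
  # close every FALSE gap shorter than merge_gap_s that sits between TRUEs
  q2 <- qual
  t <- 1
  while (t <= n) {
    if (!q2[t]) {
      g0 <- t
      while (t <= n && !q2[t]) t <- t + 1
      glen <- t - g0
      if (g0 > 1 && t <= n && glen < params$merge_gap_s)
        q2[g0:(t - 1)] <- TRUE
    } else t <- t + 1
  }
  out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                    prior_wake_s = numeric(0))
  t <- 1
  while (t <= n) {
    if (q2[t]) {
      s0 <- t
      while (t <= n && q2[t]) t <- t + 1
      dur <- t - s0
      if (dur >= params$min_atonia_s) {
        # count wake seconds backwards, tolerating short non-wake gaps
        pw <- 0; gap <- 0; i <- s0 - 1
        while (i >= 1) {
          if (wake[i]) { pw <- pw + 1; gap <- 0 }
          else { gap <- gap + 1; if (gap > params$wake_gap_s) break }
          i <- i - 1
        }
        if (pw >= params$min_prior_wake_s)
          out <- rbind(out, data.frame(onset_s = s0 - 1, duration_s = dur,
                                       prior_wake_s = pw))
      }
    } else t <- t + 1
  }
  rownames(out) <- NULL
  out
}

# binary Markov chain with given stay probability, for random flag tracks
markov_flags <- function(n, stay = 0.9, start = FALSE) {
  x <- logical(n)
  x[1] <- start
  u <- stats::runif(n)
  for (t in 2:n) x[t] <- if (u[t] < stay) x[t - 1] else !x[t - 1]
  x
}

# independent run-length scanner over labels (oracle for bouts/episodes)
scan_runs <- function(labels) {
  out <- list()
  i <- 1; n <- length(labels)
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1] == labels[i]) j <- j + 1
    out[[length(out) + 1]] <- data.frame(state = labels[i], start = i,
                                         len = j - i + 1)
    i <- j + 1
  }
  do.call(rbind, out)
}

random_hypnogram <- function(n, epoch_len = 20) {
  hypnogram(sample(c("Wake", "NREM", "REM"), n, replace = TRUE,
                   prob = c(0.45, 0.45, 0.1)), epoch_len)
}
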