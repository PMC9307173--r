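#' Simulation configuration for a narcoleptic-mouse recording
#'
#' Bundles every parameter of the semi-Markov vigilance-state generator and
#' of the state-conditioned EEG/EMG signal synthesizer. Defaults emulate an
#' orexin-knockout (OXKO) mouse during the dark phase: short wake and NREM
#' bouts producing frequent wake/NREM transitions, occasional cataplexy-like
#' events entered from sustained wakefulness, NREM delta-dominant EEG,
#' REM/cataplexy theta-dominant EEG with muscle atonia, and high variable
#' wake EMG. No quantitative spectral or EMG parameters exist for OXKO mice
#' in the literature this emulates; the numeric defaults are this package's
#' own documented conventions (see the methods vignette).
#'
#' @param sampling_rate sampling rate of synthesized signals, Hz.
#' @param duration recording length, seconds (positive integer number of 1-s
#'   bins).
#' @param zt_origin zeitgeber time of recording start, hours (12 = dark-phase
#'   onset).
#' @param mean_bout named numeric: mean bout duration in seconds for Wake,
#'   NREM, REM. `Inf` forces a single never-ending bout of that state.
#' @param bout_shape named numeric gamma shape per state (shape 2 avoids the
#'   excess of 1-s bouts an exponential would give).
#' @param rem_entry_prob probability that a NREM bout ends in REM rather than
#'   Wake.
#' @param cataplexy_hazard rate of cataplexy-like events per hour of
#'   sustained wakefulness; 0 disables the channel.
#' @param cataplexy_duration_mean,cataplexy_duration_min mean and floor of
#'   event duration, seconds.
#' @param min_wake_before_cataplexy seconds of continuous wake the generator
#'   normally enforces before an event.
#' @param decoy_fraction fraction of cataplexy-channel events deliberately
#'   preceded by only 10-39 s of wake, so the detector's prior-wake
#'   criterion has true negatives to reject.
#' @param band_weights 4 x 3 matrix (rows Wake, NREM, REM, Cataplexy;
#'   columns delta, theta, fast) of relative EEG band power per state; rows
#'   must sum to 1.
#' @param eeg_rms overall EEG RMS amplitude, microvolts.
#' @param emg_level named numeric EMG RMS in microvolts for wake, nrem,
#'   atonia; must satisfy atonia < nrem < wake.
#' @param emg_wake_cv coefficient of variation of the second-to-second wake
#'   EMG RMS.
#' @param seed default integer seed used when an operation is not given one.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(sampling_rate = 250,
                       duration = 10800,
                       zt_origin = 12,
                       mean_bout = c(Wake = 80, NREM = 100, REM = 70),
                       bout_shape = c(Wake = 2, NREM = 2, REM = 2),
                       rem_entry_prob = 0.2,
                       cataplexy_hazard = 3,
                       cataplexy_duration_mean = 40,
                       cataplexy_duration_min = 12,
                       min_wake_before_cataplexy = 60,
                       decoy_fraction = 0.1,
                       band_weights = default_band_weights(),
                       eeg_rms = 50,
                       emg_level = c(wake = 30, nrem = 10, atonia = 2),
                       emg_wake_cv = 0.3,
                       seed = 1L) {
  cfg <- list(
    sampling_rate = sampling_rate, duration = duration, zt_origin = zt_origin,
    mean_bout = mean_bout, bout_shape = bout_shape,
    rem_entry_prob = rem_entry_prob,
    cataplexy_hazard = cataplexy_hazard,
    cataplexy_duration_mean = cataplexy_duration_mean,
    cataplexy_duration_min = cataplexy_duration_min,
    min_wake_before_cataplexy = min_wake_before_cataplexy,
    decoy_fraction = decoy_fraction,
    band_weights = band_weights, eeg_rms = eeg_rms,
    emg_level = emg_level, emg_wake_cv = emg_wake_cv,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default per-state EEG band weights
#'
#' Rows are Wake, NREM, REM, Cataplexy; columns are the delta (1-4 Hz),
#' theta (6-9 Hz) and fast (10-30 Hz) bands. Cataplexy shares the REM
#' profile (theta-dominant) because the two states are spectrally alike.
#'
#' @return 4 x 3 numeric matrix with rows summing to 1.
#' @export
default_band_weights <- function() {
  m <- rbind(
    Wake      = c(delta = 0.25, theta = 0.30, fast = 0.45),
    NREM      = c(delta = 0.70, theta = 0.15, fast = 0.15),
    REM       = c(delta = 0.15, theta = 0.70, fast = 0.15),
    Cataplexy = c(delta = 0.15, theta = 0.70, fast = 0.15)
  )
  m
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$sampling_rate > 0,
    length(cfg$duration) == 1, cfg$duration > 0,
    cfg$duration == round(cfg$duration)
  )
  if (!all(c("Wake", "NREM", "REM") %in% names(cfg$mean_bout)))
    stop("mean_bout must name Wake, NREM and REM", call. = FALSE)
  if (any(cfg$mean_bout <= 0) || any(cfg$bout_shape <= 0))
    stop("bout durations and shapes must be positive", call. = FALSE)
  if (cfg$rem_entry_prob < 0 || cfg$rem_entry_prob > 1)
    stop("rem_entry_prob must lie in [0, 1]", call. = FALSE)
  if (cfg$cataplexy_hazard < 0) stop("cataplexy_hazard must be >= 0", call. = FALSE)
  if (cfg$cataplexy_duration_mean <= 0 || cfg$cataplexy_duration_min <= 0 ||
      cfg$min_wake_before_cataplexy <= 0)
    stop("cataplexy durations must be positive", call. = FALSE)
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction > 1)
    stop("decoy_fraction must lie in [0, 1]", call. = FALSE)
  bw <- cfg$band_weights
  if (!is.matrix(bw) || nrow(bw) != 4 ||
      !all(rownames(bw) == c("Wake", "NREM", "REM", "Cataplexy")))
    stop("band_weights must be a 4 x 3 matrix over the four states", call. = FALSE)
  if (any(abs(rowSums(bw) - 1) > 1e-8))
    stop("band_weights rows must each sum to 1", call. = FALSE)
  e <- cfg$emg_level
  if (!all(c("wake", "nrem", "atonia") %in% names(e)))
    stop("emg_level must name wake, nrem and atonia", call. = FALSE)
  if (!(e[["atonia"]] < e[["nrem"]] && e[["nrem"]] < e[["wake"]]))
    stop("emg_level must satisfy atonia < nrem < wake", call. = FALSE)
  invisible(cfg)
}

#' Scale a configuration by a drug effect
#'
#' An OX2R-agonist-like intervention lengthens wake bouts and suppresses the
#' cataplexy hazard; every other parameter is untouched.
#'
#' @param config a [sim_config()].
#' @param wake_bout_multiplier factor (> 0) applied to the mean Wake bout.
#' @param cataplexy_hazard_multiplier factor (> 0) applied to the hazard.
#' @return A new `sim_config`.
#' @export
apply_drug_effect <- function(config, wake_bout_multiplier,
                              cataplexy_hazard_multiplier) {
  stopifnot(inherits(config, "sim_config"))
  if (wake_bout_multiplier <= 0 || cataplexy_hazard_multiplier <= 0)
    stop("drug-effect multipliers must be positive", call. = FALSE)
  config$mean_bout[["Wake"]] <- config$mean_bout[["Wake"]] * wake_bout_multiplier
  config$cataplexy_hazard <- config$cataplexy_hazard * cataplexy_hazard_multiplier
  validate_sim_config(config)
  config
}

# Run body with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, body) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  body
}

sim_states <- c("Wake", "NREM", "REM", "Cataplexy")

#' Construct a state track from explicit per-second labels
#'
#' @param labels character vector over Wake/NREM/REM/Cataplexy, one per
#'   second.
#' @param zt_origin zeitgeber time of the first second, hours.
#' @return A `state_track`.
#' @export
state_track <- function(labels, zt_origin = 12) {
  if (length(labels) == 0) stop("labels must be non-empty", call. = FALSE)
  if (!all(labels %in% sim_states))
    stop("labels must be drawn from Wake/NREM/REM/Cataplexy", call. = FALSE)
  structure(list(labels = as.character(labels), zt_origin = zt_origin,
                 ground_truth_events = data.frame(
                   onset_s = numeric(0), duration_s = numeric(0),
                   prior_wake_s = numeric(0), decoy = logical(0))),
            class = "state_track")
}

gamma_bout <- function(mean, shape) {
  if (!is.finite(mean)) return(Inf)
  max(1L, as.integer(round(stats::rgamma(1, shape = shape,
                                         scale = mean / shape))))
}

#' Simulate a ground-truth vigilance-state sequence
#'
#' Semi-Markov generator at 1-s resolution. Bout durations are
#' gamma-distributed with the configured mean and shape. Wake bouts end in
#' NREM; NREM bouts end in REM with probability `rem_entry_prob`, else Wake;
#' REM bouts end in Wake. Cataplexy is entered only from Wake: each wake
#' bout may be interrupted by a cataplexy-like event with the configured
#' hazard (events per hour of sustained wake). Events are normally preceded
#' by at least `min_wake_before_cataplexy` seconds of continuous wake, but a
#' `decoy_fraction` of them get only 10-39 s of prior wake, so a detector
#' enforcing the 40-s prior-wake criterion has true negatives.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return A `state_track`: list with `labels` (character, one per second,
#'   half-open 1-s bins from t = 0), `zt_origin`, and a `ground_truth_events`
#'   data frame (onset_s, duration_s, prior_wake_s, decoy) describing every
#'   cataplexy-channel event the generator emitted.
#' @export
simulate_states <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$duration)
  with_seed(seed, {
    labels <- character(0)
    ev <- list()
    state <- "Wake"
    while (length(labels) < n) {
      if (state == "Wake") {
        d <- gamma_bout(config$mean_bout[["Wake"]], config$bout_shape[["Wake"]])
        rate <- config$cataplexy_hazard / 3600
        twait <- if (rate > 0) stats::rexp(1, rate) else Inf
        if (is.finite(d) && twait <= d) {
          decoy <- stats::runif(1) < config$decoy_fraction
          prior <- if (decoy) sample(10:39, 1) else
            max(ceiling(twait), config$min_wake_before_cataplexy)
          cdur <- max(config$cataplexy_duration_min,
                      round(stats::rgamma(1, shape = 2,
                                          scale = config$cataplexy_duration_mean / 2)))
          labels <- c(labels, rep("Wake", prior))
          onset <- length(labels)
          labels <- c(labels, rep("Cataplexy", cdur))
          ev[[length(ev) + 1]] <- data.frame(
            onset_s = onset, duration_s = cdur,
            prior_wake_s = prior, decoy = decoy)
          state <- "Wake"
        } else {
          labels <- c(labels, rep("Wake", min(d, n)))
          state <- "NREM"
        }
      } else if (state == "NREM") {
        d <- gamma_bout(config$mean_bout[["NREM"]], config$bout_shape[["NREM"]])
        labels <- c(labels, rep("NREM", min(d, n)))
        state <- if (stats::runif(1) < config$rem_entry_prob) "REM" else "Wake"
      } else {  # REM
        d <- gamma_bout(config$mean_bout[["REM"]], config$bout_shape[["REM"]])
        labels <- c(labels, rep("REM", min(d, n)))
        state <- "Wake"
      }
    }
    labels <- labels[seq_len(n)]
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(onset_s = numeric(0), duration_s = numeric(0),
                 prior_wake_s = numeric(0), decoy = logical(0))
    # drop events truncated away (or cut short) by the duration limit
    events <- events[events$onset_s + events$duration_s <= n, , drop = FALSE]
    rownames(events) <- NULL
    structure(list(labels = labels, zt_origin = config$zt_origin,
                   ground_truth_events = events),
              class = "state_track")
  })
}

bandlimited_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # fold to two-sided magnitude frequency
  X[f < lo | f >= hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Synthesize EEG and EMG signals from a state track
#'
#' The EEG is a mixture of three band-limited Gaussian noise carriers
#' (delta 1-4 Hz, theta 6-9 Hz, fast 10-30 Hz) whose per-second amplitudes
#' follow the square root of the current state's band weights, linearly
#' cross-faded between seconds so state boundaries are smooth within 1 s.
#' The EMG is Gaussian noise whose per-second RMS follows the state's
#' `emg_level` (wake additionally modulated by a lognormal factor with
#' coefficient of variation `emg_wake_cv`).
#'
#' @param track a `state_track` from [simulate_states()].
#' @param config the [sim_config()] that produced it.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A `recording`: list with `eeg`, `emg` (microvolts),
#'   `sampling_rate`, `zt_origin`.
#' @export
synthesize_signals <- function(track, config, seed = config$seed) {
  stopifnot(inherits(track, "state_track"), inherits(config, "sim_config"))
  nsec <- length(track$labels)
  if (nsec == 0) stop("empty state track", call. = FALSE)
  fs <- config$sampling_rate
  n <- nsec * fs
  with_seed(seed, {
    carriers <- list(
      delta = bandlimited_noise(n, fs, 0.5, 4.5),
      theta = bandlimited_noise(n, fs, 5.5, 9.5),
      fast  = bandlimited_noise(n, fs, 9.5, 30.5)
    )
    w <- config$band_weights[track$labels, , drop = FALSE]  # nsec x 3
    tmid <- (seq_len(nsec) - 0.5)                 # second midpoints
    tsmp <- (seq_len(n) - 0.5) / fs               # sample times
    eeg <- numeric(n)
    for (b in seq_along(carriers)) {
      amp <- stats::approx(tmid, sqrt(w[, b]) * config$eeg_rms,
                           xout = tsmp, rule = 2)$y
      eeg <- eeg + amp * carriers[[b]]
    }
    lvl <- c(Wake = config$emg_level[["wake"]],
             NREM = config$emg_level[["nrem"]],
             REM = config$emg_level[["atonia"]],
             Cataplexy = config$emg_level[["atonia"]])
    rms_sec <- unname(lvl[track$labels])
    is_wake <- track$labels == "Wake"
    if (any(is_wake) && config$emg_wake_cv > 0) {
      sdl <- sqrt(log(1 + config$emg_wake_cv^2))
      rms_sec[is_wake] <- rms_sec[is_wake] *
        stats::rlnorm(sum(is_wake), meanlog = -sdl^2 / 2, sdlog = sdl)
    }
    rms_smp <- stats::approx(tmid, rms_sec, xout = tsmp, rule = 2)$y
    emg <- rms_smp * stats::rnorm(n)
    structure(list(eeg = eeg, emg = emg, sampling_rate = fs,
                   zt_origin = track$zt_origin),
              class = "recording")
  })
}

#' @export
print.state_track <- function(x, ...) {
  tab <- table(factor(x$labels, levels = sim_states))
  cat("<state_track> ", length(x$labels), " s from ZT ", x$zt_origin, "\n",
      sep = "")
  print(tab)
  invisible(x)
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", length(x$eeg) / x$sampling_rate, " s @ ",
      x$sampling_rate, " Hz, ZT ", x$zt_origin, "\n", sep = "")
  invisible(x)
}
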