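#' Cataplexy detection parameters
#'
#' The three standard criteria for a cataplexy-like state in narcoleptic
#' mice: (i) an abrupt episode of nuchal atonia lasting at least 10 s,
#' (ii) theta-dominant EEG throughout the episode, (iii) at least 40 s of
#' wakefulness immediately preceding it. Detection runs at 1-s resolution
#' because a 10-s minimum is sub-epoch at the 20-s scoring length.
#'
#' @param min_atonia_s minimum episode duration, seconds (criterion i).
#' @param min_prior_wake_s minimum preceding continuous wake, seconds
#'   (criterion iii).
#' @param theta_dominance minimum theta/delta ratio for a theta-dominant
#'   second (criterion ii).
#' @param atonia_fraction EMG RMS at or below this fraction of the
#'   calibration wake reference counts as atonia.
#' @param merge_gap_s qualifying runs separated by fewer than this many
#'   non-qualifying seconds are merged before the criteria are tested.
#' @param wake_gap_s the preceding wake run tolerates non-wake gaps of at
#'   most this many seconds (robustness to single-second misclassification).
#' @param emg_smooth_s width (odd, seconds) of the running median applied to
#'   the per-second EMG RMS before thresholding; 1 disables smoothing.
#' @return An object of class `cataplexy_params`.
#' @export
cataplexy_params <- function(min_atonia_s = 10,
                             min_prior_wake_s = 40,
                             theta_dominance = 1.5,
                             atonia_fraction = 0.2,
                             merge_gap_s = 2,
                             wake_gap_s = 1,
                             emg_smooth_s = 3) {
  if (min_atonia_s <= 0 || min_prior_wake_s <= 0)
    stop("duration criteria must be positive", call. = FALSE)
  structure(list(min_atonia_s = min_atonia_s,
                 min_prior_wake_s = min_prior_wake_s,
                 theta_dominance = theta_dominance,
                 atonia_fraction = atonia_fraction,
                 merge_gap_s = merge_gap_s,
                 wake_gap_s = wake_gap_s,
                 emg_smooth_s = emg_smooth_s),
            class = "cataplexy_params")
}

#' Detect cataplexy-like episodes from per-second flags
#'
#' Core detector over three aligned per-second logical tracks. A qualifying
#' second has both atonia and theta dominance. Maximal qualifying runs
#' separated by fewer than `merge_gap_s` non-qualifying seconds are merged,
#' runs of at least `min_atonia_s` seconds are kept, and a kept run becomes
#' an event when the contiguous wake run immediately before its onset
#' (tolerating non-wake gaps of at most `wake_gap_s` seconds; gap seconds do
#' not count as wake) reaches `min_prior_wake_s` seconds.
#'
#' @param wake logical, per second: second is wakefulness.
#' @param atonia logical, per second: EMG at atonia level.
#' @param theta_dom logical, per second: theta-dominant EEG.
#' @param params a [cataplexy_params()].
#' @return Data frame with columns `onset_s`, `duration_s`, `prior_wake_s`
#'   (events in onset order; half-open second bins from t = 0).
#' @export
detect_cataplexy <- function(wake, atonia, theta_dom,
                             params = cataplexy_params()) {
  n <- length(wake)
  if (length(atonia) != n || length(theta_dom) != n)
    stop("flag tracks must have equal length", call. = FALSE)
  qual <- atonia & theta_dom
  runs <- flag_runs(qual)
  runs <- merge_runs(runs, params$merge_gap_s)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    dur <- runs$end[i] - runs$start[i] + 1
    if (dur < params$min_atonia_s) next
    pw <- prior_wake_run(wake, runs$start[i], params$wake_gap_s)
    if (pw < params$min_prior_wake_s) next
    out[[length(out) + 1]] <- data.frame(
      onset_s = as.numeric(runs$start[i] - 1),  # 0-based seconds
      duration_s = as.numeric(dur), prior_wake_s = as.numeric(pw))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(onset_s = numeric(0), duration_s = numeric(0),
               prior_wake_s = numeric(0))
}

# maximal TRUE runs of a logical vector; 1-based start/end, empty if none
flag_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# merge runs whose separating gap is < gap_s seconds
merge_runs <- function(runs, gap_s) {
  if (nrow(runs) < 2) return(runs)
  start <- runs$start[1]; end <- runs$end[1]
  out <- list()
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - end - 1 < gap_s) {
      end <- runs$end[i]
    } else {
      out[[length(out) + 1]] <- c(start, end)
      start <- runs$start[i]; end <- runs$end[i]
    }
  }
  out[[length(out) + 1]] <- c(start, end)
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# continuous wake seconds immediately before 1-based position `onset`,
# tolerating non-wake gaps of at most gap_s seconds; gap seconds don't count
prior_wake_run <- function(wake, onset, gap_s) {
  i <- onset - 1
  total <- 0L
  gap <- 0L
  while (i >= 1) {
    if (wake[i]) {
      total <- total + 1L
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap > gap_s) break
    }
    i <- i - 1
  }
  total
}

#' Detect cataplexy-like episodes in a recording
#'
#' Front end for [detect_cataplexy()]: computes per-second features,
#' calibrates the EMG reference (unless a calibration is supplied), smooths
#' the per-second EMG RMS with a short running median, and derives the
#' wake / atonia / theta-dominance flags. Wake seconds are those the epoch
#' classifier labels Wake at 1-s resolution.
#'
#' @param recording a `recording`.
#' @param params a [cataplexy_params()].
#' @param thresholds a [staging_thresholds()] used for the wake flags and
#'   calibration.
#' @param calibration optional [calibrate()] result; computed from 20-s
#'   epochs of this recording when NULL.
#' @return As [detect_cataplexy()].
#' @export
detect_cataplexy_recording <- function(recording,
                                       params = cataplexy_params(),
                                       thresholds = staging_thresholds(),
                                       calibration = NULL) {
  sec <- epoch_features(recording, 1)
  if (is.null(calibration)) {
    calibration <- calibrate(epoch_features(recording, 20), thresholds)
  }
  emg <- sec$emg_rms
  if (params$emg_smooth_s > 1)
    emg <- stats::runmed(emg, k = params$emg_smooth_s, endrule = "constant")
  ref <- calibration$wake_emg_ref
  atonia <- emg <= params$atonia_fraction * ref
  theta_dom <- sec$theta_power >=
    params$theta_dominance * sec$delta_power
  sec_sm <- sec
  sec_sm$emg_rms <- emg
  wake <- classify_epoch(sec_sm, thresholds, calibration) == "Wake"
  detect_cataplexy(wake, atonia, theta_dom, params)
}

#' Event count and latency within an analysis window
#'
#' Counts events whose onset falls inside the window and reports the
#' latency to the first event. With no event the latency is right-censored
#' at the window length (a documented convention mirroring how latency is
#' summarized when an animal never shows the behavior).
#'
#' @param events event data frame sorted by onset (from
#'   [detect_cataplexy()]).
#' @param window_s window length, seconds, from recording start.
#' @return List with `count` and `latency_s`.
#' @export
count_and_latency <- function(events, window_s) {
  inside <- events$onset_s < window_s
  n <- sum(inside)
  latency <- if (n > 0) min(events$onset_s[inside]) else window_s
  list(count = n, latency_s = latency)
}
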