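#' Staging thresholds
#'
#' Quantifies the qualitative Wake/NREM/REM scoring criteria — NREM: high
#' amplitude delta (1-4 Hz) EEG with low EMG tone; REM: theta (6-9 Hz)
#' dominant EEG with EMG atonia; Wake: everything else (fast activity with
#' high, variable EMG). The numeric values are this package's declared
#' conventions; semiautomatic scoring software in this field never publishes
#' its internal thresholds, so they are exposed here for adjustment.
#'
#' @param delta_dominance minimum delta/theta ratio for NREM (>= 1).
#' @param theta_dominance minimum theta/delta ratio for REM (>= 1).
#' @param emg_low fraction of the calibration wake EMG RMS below which tone
#'   counts as "low" (NREM criterion).
#' @param emg_atonia fraction below which tone counts as atonia (REM
#'   criterion); must be < `emg_low`.
#' @param wake_emg_cv_min minimum within-epoch EMG coefficient of variation
#'   treated as "variable" wake EMG; 0 (the default) makes Wake the pure
#'   fallback state, which is how the classifier's decision order uses it.
#' @param calibration_quantile quantile of epoch EMG RMS taken as the
#'   wake-reference level during calibration.
#' @return An object of class `staging_thresholds`.
#' @export
staging_thresholds <- function(delta_dominance = 1.5,
                               theta_dominance = 1.5,
                               emg_low = 0.5,
                               emg_atonia = 0.2,
                               wake_emg_cv_min = 0,
                               calibration_quantile = 0.9) {
  if (!(emg_atonia < emg_low && emg_low < 1))
    stop("need emg_atonia < emg_low < 1", call. = FALSE)
  if (delta_dominance < 1 || theta_dominance < 1)
    stop("dominance thresholds must be >= 1", call. = FALSE)
  structure(list(delta_dominance = delta_dominance,
                 theta_dominance = theta_dominance,
                 emg_low = emg_low, emg_atonia = emg_atonia,
                 wake_emg_cv_min = wake_emg_cv_min,
                 calibration_quantile = calibration_quantile),
            class = "staging_thresholds")
}

#' Per-recording calibration constants
#'
#' Semiautomatic scoring normalizes per animal/recording. The wake-reference
#' EMG RMS is a high quantile (default 0.9) of the per-epoch median EMG
#' RMS values —
#' in a dark-phase rodent recording the upper EMG tail is waking muscle
#' tone — and the power scale is the median total 1-30 Hz power.
#'
#' @param features an [epoch_features()] data frame with at least 30 epochs.
#' @param thresholds a [staging_thresholds()] (supplies the quantile).
#' @return List with `wake_emg_ref` (uV) and `power_scale` (uV^2).
#' @export
calibrate <- function(features, thresholds = staging_thresholds()) {
  if (nrow(features) < 30)
    stop("calibration needs at least 30 epochs", call. = FALSE)
  total <- features$delta_power + features$theta_power + features$fast_power +
    features$bin_5
  list(
    wake_emg_ref = unname(stats::quantile(emg_tone(features),
                                          thresholds$calibration_quantile)),
    power_scale = stats::median(total)
  )
}

#' Classify epochs into Wake / NREM / REM
#'
#' Decision order: REM if theta/delta >= `theta_dominance` and EMG tone <=
#' `emg_atonia` x wake reference; else NREM if delta/theta >=
#' `delta_dominance` and EMG tone <= `emg_low` x wake reference; else Wake.
#' EMG tone is the epoch's median per-second EMG RMS when available, else
#' the plain epoch RMS.
#' REM is tested first because atonia is the more specific condition. The
#' function is total: every epoch receives a label.
#'
#' @param features one or more rows of an [epoch_features()] data frame.
#' @param thresholds a [staging_thresholds()].
#' @param calibration result of [calibrate()].
#' @return Character vector of labels over Wake/NREM/REM.
#' @export
classify_epoch <- function(features, thresholds, calibration) {
  ref <- calibration$wake_emg_ref
  tone <- emg_tone(features)
  td <- features$theta_power / pmax(features$delta_power, .Machine$double.eps)
  dt <- features$delta_power / pmax(features$theta_power, .Machine$double.eps)
  lab <- rep("Wake", nrow(features))
  is_nrem <- dt >= thresholds$delta_dominance &
    tone <= thresholds$emg_low * ref
  lab[is_nrem] <- "NREM"
  is_rem <- td >= thresholds$theta_dominance &
    tone <= thresholds$emg_atonia * ref
  lab[is_rem] <- "REM"
  lab
}

#' Score a whole recording into a hypnogram
#'
#' Composes feature extraction, calibration and per-epoch classification.
#' Both the routine 20-s epoch length and the 4-s rescoring length are
#' supported. No post-hoc smoothing is applied.
#'
#' @param recording a `recording`.
#' @param epoch_len epoch length in seconds (20 or 4 in routine use).
#' @param thresholds a [staging_thresholds()].
#' @return A `hypnogram`: list with `labels` (Wake/NREM/REM), `epoch_len`,
#'   `zt_origin`.
#' @export
score_recording <- function(recording, epoch_len = 20,
                            thresholds = staging_thresholds()) {
  feats <- epoch_features(recording, epoch_len)
  cal <- calibrate(feats, thresholds)
  labels <- classify_epoch(feats, thresholds, cal)
  hypnogram(labels, epoch_len, recording$zt_origin)
}

#' Construct a hypnogram
#'
#' @param labels character vector over Wake/NREM/REM, one per epoch.
#' @param epoch_len epoch length, seconds.
#' @param zt_origin zeitgeber time of the first epoch, hours.
#' @return A `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len, zt_origin = 12) {
  if (length(labels) == 0) stop("empty hypnogram", call. = FALSE)
  if (!all(labels %in% c("Wake", "NREM", "REM")))
    stop("hypnogram labels must be Wake, NREM or REM", call. = FALSE)
  structure(list(labels = as.character(labels), epoch_len = epoch_len,
                 zt_origin = zt_origin),
            class = "hypnogram")
}

#' Predominant state within one epoch
#'
#' The state occupying the longest time in the epoch wins. Ties are broken
#' by the previous epoch's label when it is among the tied states, else by
#' the fixed priority Wake > NREM > REM.
#'
#' @param fine_labels per-second labels within one epoch (3-state alphabet).
#' @param prev label of the previous epoch, or NULL for the first epoch.
#' @return Single label.
#' @export
predominant_label <- function(fine_labels, prev = NULL) {
  if (length(fine_labels) == 0) stop("empty epoch", call. = FALSE)
  counts <- table(fine_labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  if (!is.null(prev) && prev %in% top) return(prev)
  for (s in c("Wake", "NREM", "REM")) if (s %in% top) return(s)
  top[[1]]
}

#' Ground-truth hypnogram from a simulated state track
#'
#' Reduces 1-s ground-truth labels to epoch labels with the
#' predominant-state rule. Cataplexy seconds map to REM before pooling: a
#' theta-dominant atonic state is spectrally REM-like, and the scoring
#' alphabet has only three states — separating cataplexy from REM is the
#' event detector's job, not the stager's.
#'
#' @param track a `state_track`.
#' @param epoch_len epoch length, seconds; trailing partial epoch dropped.
#' @return A `hypnogram` of predominant labels.
#' @export
track_to_hypnogram <- function(track, epoch_len) {
  lab <- track$labels
  lab[lab == "Cataplexy"] <- "REM"
  n_epoch <- floor(length(lab) / epoch_len)
  if (n_epoch < 1) stop("track shorter than one epoch", call. = FALSE)
  out <- character(n_epoch)
  prev <- NULL
  for (k in seq_len(n_epoch)) {
    seg <- lab[((k - 1) * epoch_len + 1):(k * epoch_len)]
    out[k] <- predominant_label(seg, prev)
    prev <- out[k]
  }
  hypnogram(out, epoch_len, track$zt_origin)
}

#' Pool a fine hypnogram onto a coarser epoch grid
#'
#' Majority-pools (predominant-state rule, same tie-break) blocks of a
#' fine-epoch hypnogram into larger epochs, e.g. 4-s scoring pooled per
#' 20-s block for cross-epoch-length consistency checks.
#'
#' @param hyp a `hypnogram`.
#' @param block_len target epoch length, seconds; must be a multiple of
#'   `hyp$epoch_len`.
#' @return A `hypnogram` with epoch length `block_len`.
#' @export
pool_hypnogram <- function(hyp, block_len) {
  k <- block_len / hyp$epoch_len
  if (k != round(k) || k < 1)
    stop("block_len must be a multiple of the hypnogram epoch length",
         call. = FALSE)
  n_block <- floor(length(hyp$labels) / k)
  out <- character(n_block)
  prev <- NULL
  for (b in seq_len(n_block)) {
    seg <- hyp$labels[((b - 1) * k + 1):(b * k)]
    out[b] <- predominant_label(rep(seg, each = hyp$epoch_len), prev)
    prev <- out[b]
  }
  hypnogram(out, block_len, hyp$zt_origin)
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", length(x$labels), " epochs x ", x$epoch_len,
      " s, ZT ", x$zt_origin, "\n", sep = "")
  print(table(factor(x$labels, levels = c("Wake", "NREM", "REM"))))
  invisible(x)
}

# EMG tone statistic: median per-second RMS when present, else epoch RMS
emg_tone <- function(features) {
  if (!is.null(features$emg_rms_median)) features$emg_rms_median
  else features$emg_rms
}
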