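#' Per-epoch EEG spectral and EMG amplitude features
#'
#' Tiles the recording into half-open epochs of `epoch_len` seconds (a
#' trailing partial epoch is dropped) and computes, per epoch, the mean
#' periodogram over non-overlapping 1-s rectangular windows, reported as
#' power in thirty 1-Hz bins from 1 to 30 Hz. A 1-s rectangular window has
#' exactly 1-Hz resolution, so each bin is the periodogram ordinate at the
#' integer frequency. Each window has its mean removed before transforming
#' (DC rejection only; no taper). EMG RMS and variance are computed over the
#' raw epoch samples; `emg_rms_median`, the median of the per-second EMG RMS
#' values within the epoch, is the tone statistic the classifier uses — in a
#' mixed epoch the median follows the predominant state, whereas the plain
#' RMS is dominated by a minority of high-amplitude wake seconds.
#'
#' Band powers: delta = bins 1-4 Hz, theta = bins 6-9 Hz, fast = bins
#' 10-30 Hz. The 5-Hz bin belongs to no named band, so the three band sums
#' never exceed the 1-30 Hz total.
#'
#' @param recording a `recording` (EEG + EMG, microvolts).
#' @param epoch_len epoch length in whole seconds (20 or 4 in routine use).
#' @return A data frame of class `epoch_features` with columns
#'   `epoch_index` (0-based), `epoch_len`, `bin_1` .. `bin_30` (uV^2),
#'   `delta_power`, `theta_power`, `fast_power`, `emg_rms` (uV),
#'   `emg_rms_median` (uV), `emg_var` (uV^2).
#' @export
epoch_features <- function(recording, epoch_len) {
  stopifnot(inherits(recording, "recording"))
  if (epoch_len < 1 || epoch_len != round(epoch_len))
    stop("epoch_len must be a whole number of seconds", call. = FALSE)
  fs <- recording$sampling_rate
  if (fs != round(fs) || fs < 61)
    stop("sampling rate must be an integer >= 61 Hz for 1-30 Hz bins",
         call. = FALSE)
  nsec <- floor(length(recording$eeg) / fs)
  n_epoch <- floor(nsec / epoch_len)
  if (n_epoch < 1)
    stop("recording shorter than one epoch", call. = FALSE)
  used_sec <- n_epoch * epoch_len
  ps <- second_periodograms(recording$eeg[seq_len(used_sec * fs)], fs)
  # average the 1-s periodograms within each epoch
  grp <- rep(seq_len(n_epoch), each = epoch_len)
  binpow <- rowsum(t(ps), grp) / epoch_len  # n_epoch x 30
  colnames(binpow) <- paste0("bin_", 1:30)
  emg <- matrix(recording$emg[seq_len(used_sec * fs)], nrow = epoch_len * fs)
  emg_sec <- matrix(sqrt(colMeans(
    matrix(recording$emg[seq_len(used_sec * fs)]^2, nrow = fs))),
    nrow = epoch_len)
  out <- data.frame(
    epoch_index = seq_len(n_epoch) - 1L,
    epoch_len = epoch_len,
    binpow,
    delta_power = rowSums(binpow[, 1:4, drop = FALSE]),
    theta_power = rowSums(binpow[, 6:9, drop = FALSE]),
    fast_power = rowSums(binpow[, 10:30, drop = FALSE]),
    emg_rms = sqrt(colMeans(emg^2)),
    emg_rms_median = apply(emg_sec, 2, stats::median),
    emg_var = apply(emg, 2, stats::var)
  )
  class(out) <- c("epoch_features", "data.frame")
  attr(out, "sampling_rate") <- fs
  out
}

# Periodogram of every non-overlapping 1-s window; returns a 30 x nsec
# matrix of power (uV^2) at 1..30 Hz. Scaling is such that the sum over all
# positive-frequency ordinates equals the window variance (Parseval).
second_periodograms <- function(x, fs) {
  nsec <- length(x) / fs
  m <- matrix(x, nrow = fs)
  m <- sweep(m, 2, colMeans(m))
  X <- stats::mvfft(m)
  p <- 2 * Mod(X[2:31, , drop = FALSE])^2 / fs^2
  p
}

#' Ratio of two named band powers in one epoch
#'
#' @param features one row of an [epoch_features()] data frame.
#' @param numerator_band,denominator_band one of "delta", "theta", "fast".
#' @return Dimensionless power ratio.
#' @export
band_ratio <- function(features, numerator_band, denominator_band) {
  bands <- c(delta = "delta_power", theta = "theta_power", fast = "fast_power")
  if (!numerator_band %in% names(bands) || !denominator_band %in% names(bands))
    stop("bands must be one of delta/theta/fast", call. = FALSE)
  num <- features[[bands[[numerator_band]]]]
  den <- features[[bands[[denominator_band]]]]
  if (any(den <= 0)) stop("denominator band power must be positive", call. = FALSE)
  num / den
}
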