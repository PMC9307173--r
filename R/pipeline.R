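#' Read a two-channel EEG/EMG recording from CSV
#'
#' The CSV dialect is documented and symmetric with
#' [write_recording_csv()]: leading comment lines `#key=value` carry
#' `sampling_rate_hz` and `zt_origin_h`, followed by a header line and two
#' numeric columns `eeg`, `emg` in microvolts.
#'
#' @param path file path.
#' @return A `recording`.
#' @export
read_recording_csv <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("unreadable file (empty): ", path, call. = FALSE)
  lines <- readLines(path, n = 10)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  if (is.null(meta$sampling_rate_hz))
    stop("missing #sampling_rate_hz metadata", call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("eeg", "emg") %in% names(d)))
    stop("missing channel: need both eeg and emg columns", call. = FALSE)
  structure(list(eeg = d$eeg, emg = d$emg,
                 sampling_rate = meta$sampling_rate_hz,
                 zt_origin = if (is.null(meta$zt_origin_h)) NA_real_
                             else meta$zt_origin_h),
            class = "recording")
}

#' Write a recording to the documented CSV dialect
#'
#' @param recording a `recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#sampling_rate_hz=", recording$sampling_rate),
               paste0("#zt_origin_h=", recording$zt_origin)), con)
  utils::write.csv(data.frame(eeg = recording$eeg, emg = recording$emg),
                   con, row.names = FALSE)
  invisible(path)
}

#' Write a state track as an onset/duration/state CSV
#'
#' @param track a `state_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_statetrack_csv <- function(track, path) {
  stopifnot(inherits(track, "state_track"))
  r <- rle(track$labels)
  ends <- cumsum(r$lengths)
  utils::write.csv(data.frame(onset_s = ends - r$lengths,
                              duration_s = r$lengths, state = r$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a state track written by [write_statetrack_csv()]
#'
#' @param path file path.
#' @param zt_origin zeitgeber origin to attach, hours.
#' @return A `state_track`.
#' @export
read_statetrack_csv <- function(path, zt_origin = 12) {
  d <- utils::read.csv(path)
  state_track(rep(d$state, d$duration_s), zt_origin)
}

#' Write a hypnogram CSV (epoch_index, onset_s, epoch_len_s, state)
#'
#' @param hyp a `hypnogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- length(hyp$labels)
  utils::write.csv(data.frame(epoch_index = seq_len(n) - 1L,
                              onset_s = (seq_len(n) - 1L) * hyp$epoch_len,
                              epoch_len_s = hyp$epoch_len,
                              state = hyp$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' End-to-end pipeline configuration
#'
#' @param epoch_len_s scoring epoch length, 20 or 4 seconds.
#' @param window_s `c(start_s, end_s)` analysis window.
#' @param thresholds a [staging_thresholds()].
#' @param cataplexy a [cataplexy_params()].
#' @param seed integer seed governing any randomness downstream.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(epoch_len_s = 20,
                            window_s = c(0, 10800),
                            thresholds = staging_thresholds(),
                            cataplexy = cataplexy_params(),
                            seed = 1L) {
  if (!epoch_len_s %in% c(20, 4))
    stop("epoch_len_s must be 20 or 4", call. = FALSE)
  if (window_s[1] >= window_s[2])
    stop("window start must precede end", call. = FALSE)
  structure(list(epoch_len_s = epoch_len_s, window_s = window_s,
                 thresholds = thresholds, cataplexy = cataplexy,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on one recording
#'
#' Features -> calibration -> staging -> cataplexy detection ->
#' architecture summary, deterministically. When `out_prefix` is given,
#' every stage's product is persisted (`<prefix>_hypnogram.csv`,
#' `<prefix>_events.csv`, `<prefix>_summary.csv`) together with a small run
#' manifest (`<prefix>_manifest.txt` with configuration values, seed and R
#' version).
#'
#' @param config a [pipeline_config()].
#' @param recording a `recording`.
#' @param out_prefix optional output path prefix.
#' @return List with `hypnogram`, `events`, `summary`, `features`,
#'   `calibration`.
#' @export
run_pipeline <- function(config, recording, out_prefix = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(recording, "recording"))
  feats <- epoch_features(recording, config$epoch_len_s)
  cal <- calibrate(feats, config$thresholds)
  hyp <- hypnogram(classify_epoch(feats, config$thresholds, cal),
                   config$epoch_len_s, recording$zt_origin)
  ev <- detect_cataplexy_recording(recording, config$cataplexy,
                                   config$thresholds, cal)
  win <- config$window_s
  span <- length(hyp$labels) * hyp$epoch_len
  win[2] <- min(win[2], span)
  summ <- summarize_architecture(hyp, feats, win)
  if (!is.null(out_prefix)) {
    write_hypnogram_csv(hyp, paste0(out_prefix, "_hypnogram.csv"))
    utils::write.csv(ev, paste0(out_prefix, "_events.csv"), row.names = FALSE)
    utils::write.csv(summary_row(summ), paste0(out_prefix, "_summary.csv"),
                     row.names = FALSE)
    writeLines(c(
      paste0("epoch_len_s=", config$epoch_len_s),
      paste0("window_s=", paste(win, collapse = ":")),
      paste0("seed=", config$seed),
      paste0("thresholds=", paste(names(unclass(config$thresholds)),
                                  unlist(config$thresholds), sep = ":",
                                  collapse = ",")),
      paste0("r_version=", R.version.string)),
      paste0(out_prefix, "_manifest.txt"))
  }
  list(hypnogram = hyp, events = ev, summary = summ, features = feats,
       calibration = cal)
}

#' One-row data frame view of an architecture summary
#'
#' @param summ an `architecture_summary`.
#' @return A one-row data frame (totals, episode counts, mean durations,
#'   transition counts, NREM delta power).
#' @export
summary_row <- function(summ) {
  stopifnot(inherits(summ, "architecture_summary"))
  out <- c(as.list(stats::setNames(summ$total_s,
                                   paste0("total_s_", names(summ$total_s)))),
           as.list(stats::setNames(summ$n_episodes,
                                   paste0("n_episodes_", names(summ$n_episodes)))),
           as.list(stats::setNames(summ$mean_episode_duration_s,
                                   paste0("mean_dur_s_",
                                          names(summ$mean_episode_duration_s)))),
           as.list(stats::setNames(summ$transition_counts,
                                   gsub(">", "_to_",
                                        paste0("trans_",
                                               names(summ$transition_counts))))),
           list(nrem_delta_power = summ$nrem_delta_power))
  as.data.frame(out)
}
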