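#' Episodes (maximal same-state runs) of a hypnogram
#'
#' An episode is a maximal run of identical epoch labels; intervals are
#' half-open in seconds from the hypnogram start. Episodes truncated by the
#' analysis-window edge still count as episodes (the mean-episode-duration
#' formula divides totals by episode counts with no exclusion).
#'
#' @param hyp a `hypnogram`.
#' @return Data frame with columns `state`, `onset_s`, `duration_s`.
#' @export
episodes <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  r <- rle(hyp$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(state = r$values,
             onset_s = (starts - 1) * hyp$epoch_len,
             duration_s = r$lengths * hyp$epoch_len)
}

arch_states <- c("Wake", "NREM", "REM")
arch_pairs <- c("W>N", "N>W", "N>R", "R>W", "R>N", "W>R")

# ordered-pair transition counts over the six possible stage pairs
transition_counts <- function(labels) {
  out <- stats::setNames(rep(0L, 6), arch_pairs)
  if (length(labels) > 1) {
    a <- labels[-length(labels)]
    b <- labels[-1]
    ch <- which(a != b)
    if (length(ch)) {
      key <- paste0(substr(a[ch], 1, 1), ">", substr(b[ch], 1, 1))
      tab <- table(key)
      out[names(tab)] <- as.integer(tab)
    }
  }
  out
}

#' Sleep-architecture summary over an analysis window
#'
#' Computes, on the window-clipped hypnogram: total time per state (sum of
#' epoch lengths per stage), episode counts, mean episode durations (total
#' time in a stage divided by the number of episodes of that stage),
#' ordered stage-pair transition counts, hourly wake time and hourly mean
#' wake episode duration (3600-s bins aligned to the window start, episodes
#' split at hour boundaries), and mean NREM delta power when features are
#' supplied.
#'
#' @param hyp a `hypnogram`.
#' @param features optional [epoch_features()] on the same epoch grid
#'   (needed for `nrem_delta_power`).
#' @param window `c(start_s, end_s)` half-open analysis window aligned to
#'   the epoch grid; defaults to the full hypnogram span.
#' @return An `architecture_summary` list: `total_s`, `n_episodes`,
#'   `mean_episode_duration_s` (each named by state), `transition_counts`
#'   (named by ordered pair), `hourly_wake_s`,
#'   `hourly_wake_episode_duration_s`, `nrem_delta_power`, `window`.
#' @export
summarize_architecture <- function(hyp, features = NULL, window = NULL) {
  stopifnot(inherits(hyp, "hypnogram"))
  span <- length(hyp$labels) * hyp$epoch_len
  if (is.null(window)) window <- c(0, span)
  if (window[1] %% hyp$epoch_len != 0 || window[2] %% hyp$epoch_len != 0 ||
      window[1] >= window[2] || window[1] < 0 || window[2] > span)
    stop("window must be epoch-aligned and inside the hypnogram span",
         call. = FALSE)
  idx <- (window[1] / hyp$epoch_len + 1):(window[2] / hyp$epoch_len)
  lab <- hyp$labels[idx]
  sub <- hypnogram(lab, hyp$epoch_len, hyp$zt_origin + window[1] / 3600)
  ep <- episodes(sub)

  total <- stats::setNames(vapply(arch_states, function(s)
    sum(lab == s) * hyp$epoch_len, numeric(1)), arch_states)
  neps <- stats::setNames(vapply(arch_states, function(s)
    sum(ep$state == s), numeric(1)), arch_states)
  meandur <- ifelse(neps > 0, total / neps, NA_real_)

  hours <- seq(window[1], window[2] - 1, by = 3600)
  hourly_wake <- vapply(hours, function(h0) {
    h1 <- min(h0 + 3600, window[2])
    j <- (h0 / hyp$epoch_len + 1):(h1 / hyp$epoch_len)
    sum(hyp$labels[j] == "Wake") * hyp$epoch_len
  }, numeric(1))
  # wake episodes split at hour boundaries; per-hour mean duration =
  # wake seconds in the hour / number of wake episode fragments in the hour
  wep <- ep[ep$state == "Wake", , drop = FALSE]
  wep$onset_s <- wep$onset_s + window[1]
  hourly_wdur <- vapply(hours, function(h0) {
    h1 <- min(h0 + 3600, window[2])
    lo <- pmax(wep$onset_s, h0)
    hi <- pmin(wep$onset_s + wep$duration_s, h1)
    frag <- hi - lo
    frag <- frag[frag > 0]
    if (length(frag) == 0) NA_real_ else sum(frag) / length(frag)
  }, numeric(1))

  ndp <- NA_real_
  if (!is.null(features)) {
    if (nrow(features) * features$epoch_len[1] < window[2] ||
        features$epoch_len[1] != hyp$epoch_len)
      stop("features must cover the window on the same epoch grid",
           call. = FALSE)
    is_nrem <- lab == "NREM"
    if (any(is_nrem)) ndp <- mean(features$delta_power[idx][is_nrem])
  }

  structure(list(total_s = total, n_episodes = neps,
                 mean_episode_duration_s = meandur,
                 transition_counts = transition_counts(lab),
                 hourly_wake_s = hourly_wake,
                 hourly_wake_episode_duration_s = hourly_wdur,
                 nrem_delta_power = ndp,
                 window = window),
            class = "architecture_summary")
}

#' Conditioned-place-preference score
#'
#' Time on the drug-paired side in the post-conditioning test minus time on
#' the same side in the pre-conditioning test. Both tests allow 900 s of
#' free exploration, so inputs must lie in [0, 900]; the score may be
#' negative (aversion).
#'
#' @param pre_s seconds on the (to-be) drug-paired side, pre-conditioning.
#' @param post_s seconds on the drug-paired side, post-conditioning.
#' @return List with `pre_s`, `post_s`, `score_s`.
#' @export
cpp_score <- function(pre_s, post_s) {
  if (any(c(pre_s, post_s) < 0) || any(c(pre_s, post_s) > 900))
    stop("test times must lie in [0, 900] seconds", call. = FALSE)
  list(pre_s = pre_s, post_s = post_s, score_s = post_s - pre_s)
}
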