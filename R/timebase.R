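## Trial/frame synchronization and experimental-state labelling.

#' Map photostimulation trials onto imaging frames
#'
#' Cross-references trial onset/offset times to the imaging frame clock:
#' every frame whose timestamp falls within \code{[onset, offset]} of any
#' trial is flagged excluded (photostimulation artifact frames), and each
#' trial receives its first and last covered frame index (1-based; NA when a
#' trial falls entirely between frames).
#'
#' @param trials data.frame (or DataFrame) with \code{onset} and \code{offset}
#'   columns in seconds.
#' @param frame_times strictly increasing frame timestamps (s), exposure
#'   start convention.
#' @return A list with \code{trials} (input plus \code{onset_frame},
#'   \code{offset_frame}) and \code{excluded} (logical per-frame mask, the
#'   union over trials).
#' @examples
#' ft <- seq(0, 3, by = 0.1)
#' mapTrialsToFrames(data.frame(onset = 1.0, offset = 1.5), ft)$excluded
#' @export
mapTrialsToFrames <- function(trials, frame_times) {
  trials <- as.data.frame(trials)
  if (is.unsorted(frame_times, strictly = TRUE))
    stop("frame_times must be strictly increasing")
  nF <- length(frame_times)
  dt <- if (nF > 1L) stats::median(diff(frame_times)) else 0
  excluded <- logical(nF)
  onf <- off <- rep(NA_integer_, nrow(trials))
  for (k in seq_len(nrow(trials))) {
    if (trials$onset[k] >= trials$offset[k])
      stop("trial onset must precede offset")
    if (trials$offset[k] < frame_times[1L] ||
        trials$onset[k] > frame_times[nF] + dt)
      stop(sprintf("trial %d lies outside the recording span", k))
    idx <- which(frame_times >= trials$onset[k] &
                 frame_times <= trials$offset[k])
    if (length(idx)) {
      excluded[idx] <- TRUE
      onf[k] <- idx[1L]
      off[k] <- idx[length(idx)]
    }
  }
  trials$onset_frame <- onf
  trials$offset_frame <- off
  list(trials = trials, excluded = excluded)
}

#' Label photostimulation trials with their experimental state
#'
#' Assigns each trial a primary state and an interictal sub-label. A trial is
#' \emph{baseline} if it starts before the convulsant injection;
#' \emph{ictal} if its onset lies inside a seizure interval (a seizure with an
#' undefined onset, ongoing at recording start, makes all trials before its
#' offset ictal); \emph{excluded} if its onset falls within \code{guard}
#' seconds of any seizure boundary (guard exclusion takes precedence over the
#' sub-labels); otherwise \emph{interictal}. Interictal trials within
#' \code{pre_window} seconds before a seizure onset or \code{post_window}
#' seconds after a seizure offset additionally carry the \emph{preictal} /
#' \emph{postictal} sub-label (the nearer boundary wins if both apply);
#' sub-labels are a refinement of interictal, not separate states.
#'
#' @param trials data.frame with \code{onset} (s).
#' @param seizures data.frame with \code{onset}, \code{offset} (s); onset may
#'   be NA for a seizure ongoing at recording start.
#' @param pre_window,post_window sub-label windows (s).
#' @param guard boundary guard (s).
#' @param injection_time convulsant injection time (s); trials before it are
#'   baseline.
#' @return A list with character vectors \code{state} (baseline / interictal /
#'   ictal / excluded) and \code{substate} (preictal / postictal / NA).
#' @examples
#' trl <- data.frame(onset = c(5, 40, 62, 95), offset = c(5.2, 40.2, 62.2, 95.2))
#' sz <- data.frame(onset = 60, offset = 80)
#' classifyTrialState(trl, sz, injection_time = 10)
#' @export
classifyTrialState <- function(trials, seizures, pre_window = 30,
                               post_window = 30, guard = 0.5,
                               injection_time = 0) {
  trials <- as.data.frame(trials)
  seizures <- as.data.frame(seizures)
  n <- nrow(trials)
  state <- rep("interictal", n)
  substate <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    t0 <- trials$onset[k]
    if (t0 < injection_time) {
      state[k] <- "baseline"
      next
    }
    if (nrow(seizures) == 0L) next
    on <- seizures$onset
    off <- seizures$offset
    on_eff <- ifelse(is.na(on), -Inf, on)
    if (any(t0 >= on_eff & t0 <= off)) {
      state[k] <- "ictal"
      next
    }
    bdry <- c(on[!is.na(on)], off)
    if (any(abs(t0 - bdry) <= guard)) {
      state[k] <- "excluded"
      next
    }
    d_pre <- on[!is.na(on)] - t0
    d_pre <- d_pre[d_pre > 0 & d_pre <= pre_window]
    d_post <- t0 - off
    d_post <- d_post[d_post > 0 & d_post <= post_window]
    if (length(d_pre) && (!length(d_post) || min(d_pre) < min(d_post))) {
      substate[k] <- "preictal"
    } else if (length(d_post)) {
      substate[k] <- "postictal"
    }
  }
  list(state = state, substate = substate)
}
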