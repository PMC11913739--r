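## Photostimulation response quantification: target trace extraction,
## response magnitude, decay constant, z-scoring, variability, non-target
## selection, widefield responses.
##
## Conventions shared by this module: windows are 500 ms unless stated;
## sample (n-1) standard deviations everywhere; undefined quantities
## propagate as NA and downstream aggregations skip them.

## Frames usable for a pre-window [t0 - w, t0) or post-window (t0, t0 + w].
.windowMean <- function(trace, times, lo, hi, excluded = NULL,
                        closed_left = FALSE, closed_right = TRUE) {
  sel <- if (closed_left) times >= lo else times > lo
  sel <- sel & if (closed_right) times <= hi else times < hi
  if (!is.null(excluded)) sel <- sel & !excluded
  if (!any(sel)) return(NA_real_)
  mean(trace[sel])
}

#' Extract target traces from a frame stack
#'
#' Per-frame mean over the pixels of a circular mask (default 10 um diameter)
#' centered on each photostimulation target coordinate.
#'
#' @param stack 3D array (ny x nx x frames).
#' @param coords targets x 2 matrix of coordinates (um).
#' @param diameter mask diameter (um).
#' @param pixel_size pixel pitch (um).
#' @return A targets x frames matrix.
#' @export
extractTargetTraces <- function(stack, coords, diameter = 10,
                                pixel_size = 1) {
  stopifnot(length(dim(stack)) == 3L)
  coords <- matrix(coords, ncol = 2L)
  ny <- dim(stack)[1L]
  nx <- dim(stack)[2L]
  pc <- .pixelCoords(ny, nx, pixel_size)
  m <- matrix(stack, ny * nx, dim(stack)[3L])
  out <- matrix(NA_real_, nrow(coords), ncol(m))
  for (i in seq_len(nrow(coords))) {
    d <- sqrt((pc$x - coords[i, 1])^2 + (pc$y - coords[i, 2])^2)
    sel <- d <= diameter / 2
    if (!any(sel))
      stop(sprintf("target %d mask lies outside the field of view", i))
    out[i, ] <- colMeans(m[sel, , drop = FALSE])
  }
  out
}

#' Photostimulation response magnitude
#'
#' Mean post-stimulation signal (from protocol offset to +\code{post} s)
#' minus mean pre-stimulation signal (from -\code{pre} s to protocol onset).
#' Frames flagged excluded (stimulation artifacts, including those of a
#' neighbouring trial) are dropped from the window means.
#'
#' @param trace numeric trace (typically dF/F).
#' @param times frame timestamps (s).
#' @param onset,offset trial onset and offset (s).
#' @param pre,post window lengths (s).
#' @param excluded optional per-frame exclusion mask.
#' @return Response in trace units, or NA when either window is empty.
#' @examples
#' tt <- seq(0, 4, by = 0.1)
#' tr <- as.numeric(tt > 2.2)
#' responseMagnitude(tr, tt, onset = 2, offset = 2.2)  # 1
#' @export
responseMagnitude <- function(trace, times, onset, offset, pre = 0.5,
                              post = 0.5, excluded = NULL) {
  pre_m <- .windowMean(trace, times, onset - pre, onset, excluded,
                       closed_left = TRUE, closed_right = FALSE)
  post_m <- .windowMean(trace, times, offset, offset + post, excluded)
  post_m - pre_m
}

#' Response matrix over trials and neurons
#'
#' Applies \code{\link{responseMagnitude}} to every (trial, neuron) pair of an
#' experiment, using the stated assay and the experiment's frame exclusion
#' mask.
#'
#' @param expt a \code{\linkS4class{SeizureExperiment}} (run
#'   \code{\link{addDff}} first for the default assay).
#' @param trials trial table; defaults to \code{trials(expt)}.
#' @param pre,post window lengths (s).
#' @param assay assay name.
#' @param roi_idx optional row (neuron) subset.
#' @return A trials x neurons matrix of responses with trial ids as rownames
#'   and ROI names as colnames.
#' @export
responseMatrix <- function(expt, trials = NULL, pre = 0.5, post = 0.5,
                           assay = "dff", roi_idx = NULL) {
  stopifnot(is(expt, "SeizureExperiment"))
  if (is.null(trials)) trials <- trials(expt)
  trials <- as.data.frame(trials)
  x <- SummarizedExperiment::assay(expt, assay)
  if (!is.null(roi_idx)) x <- x[roi_idx, , drop = FALSE]
  tt <- frameTimes(expt)
  excl <- excludedFrames(expt)
  out <- matrix(NA_real_, nrow(trials), nrow(x),
                dimnames = list(trials$trial_id, rownames(x)))
  for (k in seq_len(nrow(trials))) {
    pre_sel <- tt >= trials$onset[k] - pre & tt < trials$onset[k] & !excl
    post_sel <- tt > trials$offset[k] & tt <= trials$offset[k] + post & !excl
    if (!any(pre_sel) || !any(post_sel)) next
    out[k, ] <- rowMeans(x[, post_sel, drop = FALSE]) -
      rowMeans(x[, pre_sel, drop = FALSE])
  }
  out
}

#' Decay constant of the post-stimulation response
#'
#' Time after the end of stimulation at which the trace first drops strictly
#' below \code{frac} (default 63\%) of its post-stimulation maximum. The
#' crossing is searched after the post-stimulation maximum (the signal must
#' \emph{decrease} below the threshold). Trials whose trace never returns
#' below the threshold within \code{horizon} (e.g. when stimulation evoked
#' an ictal event) are undefined and return NA.
#'
#' @param trace numeric trace (e.g. mean-FOV fluorescence).
#' @param times frame timestamps (s).
#' @param stim_end end of the stimulation protocol (s).
#' @param frac threshold fraction.
#' @param horizon length (s) of the post-stimulation segment to consider.
#' @return Decay time in seconds, or NA.
#' @examples
#' tt <- seq(0, 0.5, by = 0.1)
#' decayConstant(c(1, .8, .7, .5, .4, .3), tt, stim_end = 0)  # 0.3
#' @export
decayConstant <- function(trace, times, stim_end, frac = 0.63,
                          horizon = Inf) {
  sel <- which(times >= stim_end & times <= stim_end + horizon)
  if (!length(sel)) stop("post-stimulation segment is empty")
  seg <- trace[sel]
  pk <- which.max(seg)
  thr <- frac * seg[pk]
  hit <- which(seg < thr & seq_along(seg) > pk)[1L]
  if (is.na(hit)) return(NA_real_)
  times[sel[hit]] - stim_end
}

#' Z-score a response against a neuron's baseline distribution
#'
#' \code{(r - mean(baseline)) / sd(baseline)} with the sample SD. The
#' baseline distribution is that neuron's responses from all baseline-state
#' trials.
#'
#' @param r response(s) to normalize.
#' @param baseline numeric vector of the neuron's baseline-state responses.
#' @return Z-score(s); NA when fewer than two baseline responses are defined
#'   or their SD is zero.
#' @export
zscoreToBaseline <- function(r, baseline) {
  b <- baseline[is.finite(baseline)]
  if (length(b) < 2L) return(r * NA_real_)
  s <- stats::sd(b)
  if (s == 0) return(r * NA_real_)
  (r - mean(b)) / s
}

#' Z-score a response matrix column-wise to baseline trials
#'
#' @param resp trials x neurons response matrix.
#' @param baseline_rows indices (or logical) of baseline-state trials.
#' @return Matrix of z-scores, same shape as \code{resp}.
#' @export
zscoreMatrix <- function(resp, baseline_rows) {
  out <- resp
  for (j in seq_len(ncol(resp))) {
    out[, j] <- zscoreToBaseline(resp[, j], resp[baseline_rows, j])
  }
  out
}

#' Coefficient of variation of a neuron's responses
#'
#' Sample SD over mean of the response magnitudes from all trials of one
#' state.
#'
#' @param x numeric response vector.
#' @return SD/mean, or NA when n < 2 or the mean is zero.
#' @export
responseCV <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' Select non-targeted neurons outside target exclusion zones
#'
#' Keeps non-target ROIs whose centroid lies strictly more than
#' \code{exclusion_radius} from every photostimulation target coordinate
#' (boundary-inclusive exclusion, conservative against off-target
#' activation).
#'
#' @param rois ROI data.frame with \code{x}, \code{y} and \code{is_target}.
#' @param target_coords optional targets x 2 coordinate matrix; defaults to
#'   the target ROIs' centroids.
#' @param exclusion_radius exclusion zone radius (um).
#' @return The retained non-target rows of \code{rois}.
#' @export
selectNontargets <- function(rois, target_coords = NULL,
                             exclusion_radius = 20) {
  rois <- as.data.frame(rois)
  if (is.null(target_coords)) {
    target_coords <- cbind(rois$x, rois$y)[rois$is_target, , drop = FALSE]
  }
  target_coords <- matrix(target_coords, ncol = 2L)
  nt <- rois[!rois$is_target, , drop = FALSE]
  if (!nrow(target_coords) || !nrow(nt)) return(nt)
  D <- .crossDist(cbind(nt$x, nt$y), target_coords)
  nt[apply(D, 1L, min) > exclusion_radius, , drop = FALSE]
}

#' Pre-stimulation fluorescence level
#'
#' Mean signal over a window immediately before trial onset (500 ms by
#' default; a 250 ms variant is used for neuropil measures at
#' photostimulation trials).
#'
#' @param trace numeric trace.
#' @param times frame timestamps (s).
#' @param onset trial onset (s).
#' @param window window length (s).
#' @param excluded optional per-frame exclusion mask.
#' @return Mean level, or NA when the window holds no usable frames.
#' @export
prestimLevel <- function(trace, times, onset, window = 0.5,
                         excluded = NULL) {
  .windowMean(trace, times, onset - window, onset, excluded,
              closed_left = TRUE, closed_right = FALSE)
}

#' Widefield photostimulation response magnitude
#'
#' Mean post-stimulation signal (0 to +\code{post} s after the high-speed
#' shutter release) minus mean pre-stimulation signal (-\code{pre} s to 0
#' before shutter deployment). Frames during shutter closure are ignored.
#'
#' @param trace mean-FOV fluorescence trace.
#' @param times frame timestamps (s).
#' @param shutter_deploy,shutter_release shutter window boundaries (s).
#' @param pre,post window lengths (s).
#' @param excluded optional per-frame exclusion mask.
#' @return Response in trace units, or NA for empty windows.
#' @export
widefieldResponse <- function(trace, times, shutter_deploy, shutter_release,
                              pre = 0.5, post = 0.5, excluded = NULL) {
  shut <- times >= shutter_deploy & times <= shutter_release
  excl <- if (is.null(excluded)) shut else (excluded | shut)
  pre_m <- .windowMean(trace, times, shutter_deploy - pre, shutter_deploy,
                       excl, closed_left = TRUE, closed_right = FALSE)
  post_m <- .windowMean(trace, times, shutter_release,
                        shutter_release + post, excl)
  post_m - pre_m
}
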