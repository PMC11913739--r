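## Seizure-wavefront geometry: signed distances, proximal/distal classes,
## rolling distance profiles, trial-centered frame averages, invasion timing.

#' Signed shortest distance to the seizure wavefront
#'
#' Perpendicular distance from each point to the infinite line through the
#' two wavefront coordinates (the annotation line spans the image, so the
#' segment extent is irrelevant). Positive distances lie on the penumbral
#' (not-yet-recruited) side defined by the annotation's reference point.
#'
#' @param points n x 2 matrix (or length-2 vector) of coordinates (um).
#' @param front a \code{\linkS4class{FrontLine}}.
#' @return Signed distances (um).
#' @examples
#' fl <- frontLine(c(0, -100), c(0, 100), ref = c(10, 0))
#' distanceToFront(c(50, 30), fl)  # +50
#' @export
distanceToFront <- function(points, front) {
  stopifnot(is(front, "FrontLine"))
  validObject(front)
  points <- matrix(points, ncol = 2L)
  v <- front@p2 - front@p1
  nrm <- c(-v[2], v[1]) / sqrt(sum(v^2))
  d <- (points[, 1] - front@p1[1]) * nrm[1] +
       (points[, 2] - front@p1[2]) * nrm[2]
  side <- sign(sum((front@ref - front@p1) * nrm))
  d * side
}

#' Classify non-targets as proximal or distal to the wavefront
#'
#' Proximal: signed distance in [0, 100) um ahead of the wavefront; distal:
#' beyond 200 um; everything else (including already-recruited territory at
#' negative distances) is intermediate.
#'
#' @param d numeric signed distances (um).
#' @return Factor with levels proximal, intermediate, distal.
#' @export
classifyProximalDistal <- function(d) {
  out <- rep("intermediate", length(d))
  out[d >= 0 & d < 100] <- "proximal"
  out[d > 200] <- "distal"
  factor(out, levels = c("proximal", "intermediate", "distal"))
}

#' Rolling distance-binned profile
#'
#' Sliding-window means of \code{values} over \code{distances}: bins of width
#' \code{bin_width} centered on a grid with spacing \code{step}, each
#' reporting mean, t-based confidence interval and count. Bins with fewer
#' than \code{n_min} values are flagged (\code{kept = FALSE}) and should be
#' suppressed from displays. 40 um bins are the convention for target
#' response profiles, 20 um for neuropil profiles.
#'
#' @param values numeric values (e.g. baseline-referenced z-scores).
#' @param distances numeric distances (um), aligned with \code{values}.
#' @param bin_width bin width (um).
#' @param step grid spacing of bin centers (um).
#' @param n_min minimum count for a reportable bin.
#' @param conf confidence level of the interval.
#' @return data.frame with \code{center}, \code{mean}, \code{lo}, \code{hi},
#'   \code{n}, \code{kept}; zero rows for empty input.
#' @export
rollingProfile <- function(values, distances, bin_width = 40, step = 5,
                           n_min = 5, conf = 0.95) {
  ok <- is.finite(values) & is.finite(distances)
  values <- values[ok]
  distances <- distances[ok]
  if (!length(values))
    return(data.frame(center = numeric(0), mean = numeric(0),
                      lo = numeric(0), hi = numeric(0), n = integer(0),
                      kept = logical(0)))
  centers <- seq(floor(min(distances) / step) * step,
                 ceiling(max(distances) / step) * step, by = step)
  res <- lapply(centers, function(ctr) {
    sel <- distances >= ctr - bin_width / 2 & distances < ctr + bin_width / 2
    n <- sum(sel)
    if (n == 0L)
      return(data.frame(center = ctr, mean = NA_real_, lo = NA_real_,
                        hi = NA_real_, n = 0L, kept = FALSE))
    m <- mean(values[sel])
    hw <- .ciHalfWidth(values[sel], conf)
    data.frame(center = ctr, mean = m, lo = m - hw, hi = m + hw, n = n,
               kept = n >= n_min)
  })
  do.call(rbind, res)
}

#' Trial-centered frame average
#'
#' Pixel-wise mean of \code{n_frames} frames centered on a trial's frame
#' index — the low-noise image used to annotate the seizure wavefront at each
#' photostimulation trial. The window is clipped at the recording edges with
#' a warning.
#'
#' @param stack 3D array (ny x nx x frames).
#' @param center_frame frame index at the trial.
#' @param n_frames number of frames to average.
#' @return A 2D (ny x nx) matrix.
#' @export
trialFrameAverage <- function(stack, center_frame, n_frames = 100) {
  stopifnot(length(dim(stack)) == 3L)
  nt <- dim(stack)[3L]
  lo <- center_frame - floor((n_frames - 1) / 2)
  hi <- center_frame + ceiling((n_frames - 1) / 2)
  if (lo < 1L || hi > nt) {
    warning("averaging window clipped at recording edge")
    lo <- max(1L, lo)
    hi <- min(nt, hi)
  }
  if (hi == lo) return(stack[, , lo])
  apply(stack[, , lo:hi, drop = FALSE], c(1L, 2L), mean)
}

#' Seizure invasion time of a neuron
#'
#' The initiation of the greatest upward deflection leading to the
#' within-seizure maximum of the raw fluorescence trace, operationalized as
#' the last local minimum before the in-window argmax after light smoothing
#' (3-frame moving average). Only minima in the lower half of the window's
#' range qualify, so shallow noise dips on an already-elevated (ictal
#' plateau) signal are not mistaken for the start of the rise. Returns the
#' seizure onset when the rise is already under way at onset.
#'
#' @param trace raw fluorescence trace.
#' @param times frame timestamps (s).
#' @param onset,offset seizure interval (s).
#' @param smooth_window smoothing window (frames).
#' @return Invasion time (s), or NA for a flat trace.
#' @export
invasionTime <- function(trace, times, onset, offset, smooth_window = 3) {
  win <- which(times >= onset & times <= offset)
  if (!length(win)) stop("seizure window contains no frames")
  y <- .movingAverage(trace[win], smooth_window)
  if (max(y) - min(y) < .Machine$double.eps^0.5) return(NA_real_)
  m <- which.max(y)
  if (m == 1L) return(times[win[1L]])
  half <- min(y) + 0.5 * (max(y) - min(y))
  j <- NA_integer_
  for (i in seq_len(m - 1L)) {
    left_ok <- if (i == 1L) TRUE else y[i] <= y[i - 1L]
    if (left_ok && y[i] < y[i + 1L] && y[i] <= half) j <- i
  }
  if (is.na(j)) return(times[win[1L]])
  times[win[j]]
}
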