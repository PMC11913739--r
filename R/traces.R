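## Trace-level quantities: dF/F normalization, annulus neuropil, activity
## rate, seizure-aligned normalization, recruitment delay, cross-correlation
## lag, neighbour lookup and ROI overlap filtering.

#' Normalize fluorescence traces to their mean (dF/F)
#'
#' Divides each trace by its mean computed over non-excluded frames
#' (photostimulation-artifact and ictal frames are the usual exclusions) after
#' subtracting it: \code{(F - m) / m}. Excluded frames are still transformed.
#' The result is invariant to rescaling the raw trace.
#'
#' @param x numeric vector, or a neurons x frames matrix.
#' @param excluded logical per-frame mask of frames to drop from the mean.
#' @return An object of the same shape as \code{x}. Matrix rows whose
#'   included-frame mean is not positive are set to NA with a warning; a
#'   vector input with a non-positive mean is an error.
#' @examples
#' dffNormalize(c(1, 3))                       # -0.5, 0.5
#' dffNormalize(c(1, 3, 100), c(FALSE, FALSE, TRUE))
#' @export
dffNormalize <- function(x, excluded = NULL) {
  if (is.matrix(x)) {
    if (is.null(excluded)) excluded <- logical(ncol(x))
    stopifnot(length(excluded) == ncol(x))
    if (!any(!excluded)) stop("all frames are excluded")
    m <- rowMeans(x[, !excluded, drop = FALSE])
    bad <- !is.finite(m) | m <= 0
    if (any(bad)) {
      warning(sprintf("%d ROI(s) with non-positive mean rejected from dF/F: %s",
                      sum(bad),
                      paste(utils::head(which(bad), 5L), collapse = ", ")))
      m[bad] <- NA_real_
    }
    return((x - m) / m)
  }
  if (is.null(excluded)) excluded <- logical(length(x))
  stopifnot(length(excluded) == length(x))
  m <- mean(x[!excluded])
  if (!is.finite(m) || m <= 0)
    stop("trace mean over included frames must be positive")
  (x - m) / m
}

#' Add a dF/F assay to an experiment
#'
#' Computes the \code{"dff"} assay from \code{"fluorescence"}, excluding
#' photostimulation-artifact frames and (by default) ictal frames from each
#' trace's mean.
#'
#' @param expt a \code{\linkS4class{SeizureExperiment}}.
#' @param exclude_ictal also drop frames inside seizure intervals from the
#'   normalizing mean.
#' @return The experiment with a \code{"dff"} assay added.
#' @export
addDff <- function(expt, exclude_ictal = TRUE) {
  stopifnot(is(expt, "SeizureExperiment"))
  excl <- excludedFrames(expt)
  if (exclude_ictal && nrow(seizures(expt))) {
    tt <- frameTimes(expt)
    sz <- as.data.frame(seizures(expt))
    for (k in seq_len(nrow(sz))) {
      on <- if (is.na(sz$onset[k])) -Inf else sz$onset[k]
      excl <- excl | (tt >= on & tt <= sz$offset[k])
    }
  }
  raw <- SummarizedExperiment::assay(expt, "fluorescence")
  SummarizedExperiment::assay(expt, "dff") <- dffNormalize(raw, excl)
  expt
}

#' Annulus neuropil trace around a point
#'
#' Per-frame mean intensity over the pixels whose centers lie in the annulus
#' \code{r_in <= d < r_out} around \code{center}, excluding any pixels in
#' \code{exclude} (e.g. other labelled somata inside the annulus).
#'
#' @param stack 3D array (ny x nx x frames), e.g. from
#'   \code{\link{renderFrames}}.
#' @param center numeric(2) annulus center (um).
#' @param r_in,r_out annulus radii (um); defaults follow the 20/100 um
#'   convention used for local-neuropil recruitment.
#' @param pixel_size pixel pitch (um).
#' @param exclude integer linear pixel indices (column-major) to drop, or a
#'   list of such vectors.
#' @return Numeric per-frame trace.
#' @export
annulusNeuropil <- function(stack, center, r_in = 20, r_out = 100,
                            pixel_size = 1, exclude = NULL) {
  stopifnot(length(dim(stack)) == 3L)
  ny <- dim(stack)[1L]
  nx <- dim(stack)[2L]
  pc <- .pixelCoords(ny, nx, pixel_size)
  d <- sqrt((pc$x - center[1])^2 + (pc$y - center[2])^2)
  sel <- d >= r_in & d < r_out
  if (!is.null(exclude)) {
    if (is.list(exclude)) exclude <- unique(unlist(exclude))
    sel[exclude] <- FALSE
  }
  if (!any(sel))
    stop("annulus contains no pixels after exclusions")
  m <- matrix(stack, ny * nx, dim(stack)[3L])
  colMeans(m[sel, , drop = FALSE])
}

#' Activity rate from a deconvolved trace
#'
#' Area under the deconvolved activity signal divided by the covered
#' duration: \code{sum(x) * dt / (n * dt)}.
#'
#' @param x numeric vector or a neurons x frames matrix of non-negative
#'   deconvolved activity.
#' @param frame_rate imaging rate (Hz).
#' @param frames optional frame subset (indices or logical) over which to
#'   compute the rate.
#' @return Rate(s) in a.u./s; one value per row for matrix input.
#' @examples
#' activityRate(c(0, 2, 0), frame_rate = 10)  # 0.667
#' @export
activityRate <- function(x, frame_rate, frames = NULL) {
  .assertScalar(frame_rate, "frame_rate", lower = 1e-12)
  if (is.matrix(x)) {
    if (!is.null(frames)) x <- x[, frames, drop = FALSE]
    if (ncol(x) == 0L) stop("no frames selected")
    return(rowMeans(x))
  }
  if (!is.null(frames)) x <- x[frames]
  if (!length(x)) stop("no frames selected")
  if (any(!is.finite(x))) stop("trace must be finite")
  mean(x)
}

#' Baseline-window normalization around seizure onset
#'
#' Subtracts the mean of a pre-onset baseline window (default -1.5 to -0.5 s
#' relative to onset) from the whole trace, so seizure-aligned traces from
#' different neurons are comparable.
#'
#' @param trace numeric trace.
#' @param times frame timestamps (s).
#' @param onset seizure onset (s).
#' @param base_window numeric(2), window relative to onset (s).
#' @param excluded optional logical per-frame exclusion mask.
#' @return The normalized trace (same length as the input).
#' @export
alignToSeizure <- function(trace, times, onset, base_window = c(-1.5, -0.5),
                           excluded = NULL) {
  stopifnot(length(trace) == length(times))
  rel <- times - onset
  sel <- rel >= base_window[1] & rel < base_window[2]
  if (!is.null(excluded)) sel <- sel & !excluded
  if (!any(sel))
    stop("baseline window contains no usable frames")
  trace - mean(trace[sel])
}

#' Delay to seizure recruitment
#'
#' Time after seizure onset at which a trace first reaches \code{frac} of its
#' maximum within the seizure interval. 0.65 is the within-annulus
#' recruitment convention; 0.85 the stricter one for ordering neurons by
#' recruitment. No sub-frame interpolation is performed: the delay is the
#' timestamp of the first at-or-above frame.
#'
#' @param trace numeric trace (typically dF/F, baseline-normalized).
#' @param times frame timestamps (s).
#' @param onset,offset seizure interval (s).
#' @param frac threshold fraction of the within-seizure maximum; must be given
#'   explicitly (the 0.65 vs 0.85 choice is analysis-dependent).
#' @param excluded optional per-frame exclusion mask (photostimulation
#'   artifact frames must not enter the within-seizure maximum).
#' @return Delay in seconds (>= 0), or NA if the trace never reaches the
#'   threshold within the seizure.
#' @examples
#' tt <- seq(0, 10, by = 0.1)
#' tr <- as.numeric(tt >= 4)
#' recruitmentDelay(tr, tt, onset = 2, offset = 8, frac = 0.65)  # 2.0
#' @export
recruitmentDelay <- function(trace, times, onset, offset, frac,
                             excluded = NULL) {
  .assertScalar(frac, "frac", lower = 0, upper = 1)
  win <- which(times >= onset & times <= offset)
  if (!is.null(excluded)) win <- win[!excluded[win]]
  if (!length(win)) stop("seizure window contains no frames")
  thr <- frac * max(trace[win])
  hit <- win[which(trace[win] >= thr)[1L]]
  if (is.na(hit)) return(NA_real_)
  times[hit] - onset
}

#' Cross-correlation lag between two traces
#'
#' Signed lag (s) maximizing the Pearson correlation between mean-subtracted
#' traces over integer frame shifts up to \code{max_lag}. Positive lag means
#' \code{b} lags \code{a}. Ties are broken towards the smaller absolute lag.
#'
#' @param a,b numeric traces of equal length (already windowed, e.g. 1 s
#'   before seizure onset to 1 s after termination).
#' @param frame_rate imaging rate (Hz).
#' @param max_lag maximum absolute lag (s).
#' @return A list with \code{lag} (s), \code{correlation} at that lag, and
#'   \code{lag_frames}. \code{lag} is NA for zero-variance input.
#' @examples
#' a <- sin(seq(0, 6 * pi, length.out = 200))
#' b <- c(rep(0, 5), a[1:195])
#' xcorrLag(a, b, frame_rate = 20)$lag  # +0.25
#' @export
xcorrLag <- function(a, b, frame_rate, max_lag = 2) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  K <- floor(max_lag * frame_rate)
  if (n <= 2 * K)
    stop("window must be longer than twice the maximum lag")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(lag = NA_real_, correlation = NA_real_,
                lag_frames = NA_integer_))
  lags <- order(abs(seq(-K, K)))  # visit small |lag| first for tie-breaking
  lags <- seq(-K, K)[lags]
  best <- -Inf
  best_lag <- 0L
  for (L in lags) {
    if (L >= 0) {
      r <- stats::cor(a[seq_len(n - L)], b[seq_len(n - L) + L])
    } else {
      r <- stats::cor(a[seq_len(n + L) - L], b[seq_len(n + L)])
    }
    if (is.finite(r) && r > best + 1e-12) {
      best <- r
      best_lag <- L
    }
  }
  list(lag = best_lag / frame_rate, correlation = best,
       lag_frames = as.integer(best_lag))
}

#' Nearest excitatory neighbour of an inhibitory neuron
#'
#' @param roi_id id of the (inhibitory) reference neuron.
#' @param rois data.frame with \code{roi_id}, \code{x}, \code{y} (um) and
#'   \code{is_inhibitory}.
#' @param radius search radius (um).
#' @return roi_id of the nearest non-inhibitory neuron within \code{radius},
#'   or NA if none.
#' @export
nearestExcitatory <- function(roi_id, rois, radius = 100) {
  rois <- as.data.frame(rois)
  self <- rois[rois$roi_id == roi_id, , drop = FALSE]
  if (nrow(self) != 1L) stop("roi_id not found")
  cand <- rois[!rois$is_inhibitory & rois$roi_id != roi_id, , drop = FALSE]
  if (!nrow(cand)) return(NA_integer_)
  d <- .distTo(cbind(cand$x, cand$y), c(self$x, self$y))
  keep <- d <= radius
  if (!any(keep)) return(NA_integer_)
  cand$roi_id[keep][which.min(d[keep])]
}

#' Drop putative-excitatory ROIs overlapping inhibitory ROIs
#'
#' Removes non-inhibitory ROIs whose pixel mask shares more than
#' \code{max_overlap} of its pixels with any inhibitory ROI mask (guards
#' against misclassified or contaminated segmentation). Inhibitory ROIs are
#' always kept.
#'
#' @param rois data.frame with \code{roi_id} and \code{is_inhibitory}.
#' @param masks list of integer pixel-index vectors parallel to \code{rois}
#'   rows, e.g. from \code{\link{roiMasks}}.
#' @param max_overlap maximum tolerated overlap fraction (shared pixels /
#'   own pixels).
#' @return The filtered ROI table.
#' @export
overlapFilter <- function(rois, masks, max_overlap = 0.05) {
  rois <- as.data.frame(rois)
  stopifnot(length(masks) == nrow(rois))
  if (any(lengths(masks) == 0L)) stop("all pixel masks must be non-empty")
  inh <- which(rois$is_inhibitory)
  keep <- rep(TRUE, nrow(rois))
  if (length(inh)) {
    inh_px <- unique(unlist(masks[inh]))
    for (i in which(!rois$is_inhibitory)) {
      frac <- sum(masks[[i]] %in% inh_px) / length(masks[[i]])
      if (frac > max_overlap) keep[i] <- FALSE
    }
  }
  rois[keep, , drop = FALSE]
}
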