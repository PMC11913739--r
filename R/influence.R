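## Influence of photostimulated targets on non-targeted neurons.
##
## With simultaneous ensemble stimulation there are no true no-stimulation
## control trials, so the predicted response of every non-target on a trial
## is the mean response of all non-targets on that trial (their responses are
## strongly correlated within a trial). The influence value is the deviation
## from this prediction, normalized by its across-trial SD — which makes the
## metric invariant to per-trial additive offsets shared by all non-targets.

#' Predicted non-target response for one trial
#'
#' Mean photostimulation response over all non-targeted neurons of a trial,
#' used as each non-target's predicted response on that trial.
#'
#' @param r numeric vector of non-target responses on one trial.
#' @return The mean over defined responses; NA when fewer than two are
#'   defined.
#' @export
predictedResponse <- function(r) {
  ok <- is.finite(r)
  if (sum(ok) < 2L) return(NA_real_)
  mean(r[ok])
}

#' Trial-wise influence metric for non-targeted neurons
#'
#' For a trials x non-targets response matrix computes, per trial t and
#' neuron j, the difference \code{d[t, j] = r[t, j] - p[t]} from the trial's
#' predicted response \code{p[t]} (mean over non-targets), and the influence
#' \code{I[t, j] = d[t, j] / sd_t(d[, j])} with the sample SD over trials.
#' Neurons with zero or undefined SD get NA influence.
#'
#' @param resp trials x non-targets numeric response matrix (at least two
#'   trials).
#' @return A list with matrices \code{difference} and \code{influence}
#'   (trials x non-targets) and the per-trial \code{predicted} vector.
#' @examples
#' influenceMetric(rbind(c(1, 3), c(2, 6)))$influence
#' @export
influenceMetric <- function(resp) {
  resp <- as.matrix(resp)
  if (nrow(resp) < 2L)
    stop("influence needs at least two trials")
  p <- apply(resp, 1L, predictedResponse)
  d <- resp - p
  sdj <- apply(d, 2L, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2L) return(NA_real_)
    stats::sd(col)
  })
  sdj[!is.na(sdj) & sdj == 0] <- NA_real_
  I <- sweep(d, 2L, sdj, "/")
  list(difference = d, influence = I, predicted = p)
}

#' Artificial (sham) stimulation trials
#'
#' Interleaves one artificial trial at the midpoint between each pair of
#' consecutive real trial onsets, with the same protocol duration, as an
#' alternative to true no-stimulation controls. A sham is only emitted when
#' the surrounding gap accommodates the sham protocol plus its pre and post
#' analysis windows without touching the flanking real trials.
#'
#' @param trials data.frame with \code{onset}, \code{offset} (s), sorted or
#'   not.
#' @param pre,post analysis window lengths (s) that must fit around the sham.
#' @return data.frame of sham trials (trial_id, onset, offset,
#'   modality = "artificial"); zero rows when fewer than two real trials.
#' @examples
#' artificialTrials(data.frame(onset = c(0, 10), offset = c(1, 11)))
#' @export
artificialTrials <- function(trials, pre = 0.5, post = 0.5) {
  trials <- as.data.frame(trials)
  trials <- trials[order(trials$onset), , drop = FALSE]
  out <- data.frame(trial_id = integer(0), onset = numeric(0),
                    offset = numeric(0), modality = character(0))
  if (nrow(trials) < 2L) return(out)
  for (k in seq_len(nrow(trials) - 1L)) {
    dur <- trials$offset[k] - trials$onset[k]
    mid <- (trials$onset[k] + trials$onset[k + 1L]) / 2
    if (mid - pre <= trials$offset[k]) next
    if (mid + dur + post >= trials$onset[k + 1L]) next
    out <- rbind(out, data.frame(trial_id = k, onset = mid,
                                 offset = mid + dur,
                                 modality = "artificial"))
  }
  out$trial_id <- seq_len(nrow(out))
  out
}

#' Influence versus target distance profile
#'
#' Attributes each non-target's trial influences to every target within
#' \code{max_dist} and bins them by pairwise (target, non-target) distance.
#' Under simultaneous ensemble stimulation single-target causal attribution
#' is not possible, so a non-target contributes the same influence values to
#' every nearby target's bin. The bin summary is computed over per-pair
#' across-trial means; the SEM therefore respects the clustering of trials
#' within a pair.
#'
#' @param influence trials x non-targets influence matrix (from
#'   \code{\link{influenceMetric}}).
#' @param nontarget_coords non-targets x 2 centroid matrix (um), columns
#'   aligned with \code{influence}.
#' @param target_coords targets x 2 coordinate matrix (um).
#' @param max_dist maximum pair distance (um).
#' @param breaks distance bin edges (um).
#' @return data.frame with \code{lo}, \code{hi}, \code{center}, \code{mean},
#'   \code{sem}, \code{n_pairs}.
#' @export
influenceVsDistance <- function(influence, nontarget_coords, target_coords,
                                max_dist = 400, breaks = seq(0, 400, by = 40)) {
  influence <- as.matrix(influence)
  nontarget_coords <- matrix(nontarget_coords, ncol = 2L)
  target_coords <- matrix(target_coords, ncol = 2L)
  stopifnot(nrow(nontarget_coords) == ncol(influence))
  D <- .crossDist(target_coords, nontarget_coords)
  pair_mean <- colMeans(influence, na.rm = TRUE)  # per non-target
  lo <- utils::head(breaks, -1L)
  hi <- utils::tail(breaks, -1L)
  means <- sems <- rep(NA_real_, length(lo))
  ns <- integer(length(lo))
  for (b in seq_along(lo)) {
    sel <- which(D > lo[b] & D <= hi[b] & D <= max_dist, arr.ind = TRUE)
    if (b == 1L)  # include pairs at exactly zero distance in the first bin
      sel <- rbind(sel, which(D == lo[1L], arr.ind = TRUE))
    if (!nrow(sel)) next
    vals <- pair_mean[sel[, 2L]]
    vals <- vals[is.finite(vals)]
    ns[b] <- length(vals)
    if (!length(vals)) next
    means[b] <- mean(vals)
    if (length(vals) > 1L)
      sems[b] <- stats::sd(vals) / sqrt(length(vals))
  }
  data.frame(lo = lo, hi = hi, center = (lo + hi) / 2, mean = means,
             sem = sems, n_pairs = ns)
}

#' Total target versus non-target responses per trial
#'
#' Sums response magnitudes over all targets and over all non-targets for
#' each trial, z-scores both totals within the replicate, and reports their
#' correlation — the trial-by-trial coupling between directly evoked and
#' propagated activity.
#'
#' @param target_resp trials x targets response matrix.
#' @param nontarget_resp trials x non-targets response matrix (same trials).
#' @return A list with \code{totals} (data.frame: trial, target_total_z,
#'   nontarget_total_z) and \code{correlation} (NA with fewer than three
#'   trials or degenerate totals).
#' @export
targetVsNontargetTotals <- function(target_resp, nontarget_resp) {
  target_resp <- as.matrix(target_resp)
  nontarget_resp <- as.matrix(nontarget_resp)
  stopifnot(nrow(target_resp) == nrow(nontarget_resp))
  zin <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x)) / s
  }
  tt <- rowSums(target_resp)
  nt <- rowSums(nontarget_resp)
  zt <- zin(tt)
  znt <- zin(nt)
  r <- if (nrow(target_resp) >= 3L && all(is.finite(zt)) &&
           all(is.finite(znt))) stats::cor(zt, znt) else NA_real_
  list(totals = data.frame(trial = seq_along(tt), target_total_z = zt,
                           nontarget_total_z = znt),
       correlation = r)
}
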