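## Photostimulation-seizure phase analysis: event phases on the
## inter-stimulus cycle and the V-test for circular non-uniformity.

#' Event phases within the photostimulation cycle
#'
#' Assigns each event (e.g. a seizure onset) the signed time difference to
#' its nearest photostimulation trial, bins it into \code{bin}-second bins
#' (the zero bin spans -bin/2 to +bin/2 around stimulation), and converts the
#' bin to a phase angle \code{2*pi*k*bin/period} wrapped to [-pi, pi). With a
#' variable stimulation grid each event uses the local inter-stimulus
#' interval containing it as its period. Events outside the stimulus span are
#' dropped and counted.
#'
#' @param event_times event times (s).
#' @param stim_times photostimulation onset times (s), at least two.
#' @param bin phase bin width (s).
#' @return A \code{\linkS4class{PhaseSet}}.
#' @examples
#' ps <- eventPhases(c(10, 14.8), stim_times = seq(0, 50, by = 10))
#' ps@angles
#' @export
eventPhases <- function(event_times, stim_times, bin = 1) {
  stim_times <- sort(stim_times)
  if (length(stim_times) < 2L)
    stop("need at least two stimulation times")
  gaps <- diff(stim_times)
  lo <- stim_times[1L] - gaps[1L] / 2
  hi <- stim_times[length(stim_times)] + gaps[length(gaps)] / 2
  keep <- event_times >= lo & event_times <= hi
  dropped <- sum(!keep)
  ev <- event_times[keep]
  angles <- raw_angles <- numeric(length(ev))
  for (i in seq_along(ev)) {
    k <- which.min(abs(ev[i] - stim_times))
    dt <- ev[i] - stim_times[k]
    period <- if (dt >= 0) {
      if (k < length(stim_times)) gaps[k] else gaps[length(gaps)]
    } else {
      if (k > 1L) gaps[k - 1L] else gaps[1L]
    }
    m <- round(dt / bin)
    angles[i] <- .wrapAngle(2 * pi * m * bin / period)
    raw_angles[i] <- .wrapAngle(2 * pi * dt / period)
  }
  new("PhaseSet", angles = angles, raw_angles = raw_angles,
      bin_width = bin, stim_period = stats::median(gaps),
      n_events = length(ev), n_dropped = as.integer(dropped))
}

#' V-test for circular non-uniformity towards a known direction
#'
#' One-sample test of whether angles are non-uniformly concentrated at the
#' specified mean direction \code{mu} (0 rad = the photostimulation-locked
#' bin). With mean resultant length R at direction theta-bar, the statistic
#' is \code{V = R * cos(theta_bar - mu)} and \code{u = V * sqrt(2 n)} is
#' compared against the upper tail of the standard normal (one-sided, as the
#' test prescribes).
#'
#' @param angles numeric angles (radians), or a
#'   \code{\linkS4class{PhaseSet}} (its binned angles are used).
#' @param mu hypothesized mean direction (radians).
#' @return An object of class \code{"htest"} with the statistic \code{u}, the
#'   p-value, and \code{Vbar} and \code{n} in \code{estimate} /
#'   \code{parameter}.
#' @examples
#' vTest(rep(0, 4))       # u = sqrt(8), p ~ 0.0023
#' @export
vTest <- function(angles, mu = 0) {
  if (is(angles, "PhaseSet")) angles <- angles@angles
  n <- length(angles)
  if (n < 1L) stop("need at least one angle")
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  R <- sqrt(C^2 + S^2)
  theta <- atan2(S, C)
  Vbar <- R * cos(theta - mu)
  u <- Vbar * sqrt(2 * n)
  p <- stats::pnorm(u, lower.tail = FALSE)
  structure(
    list(statistic = c(u = u), p.value = p,
         estimate = c(Vbar = Vbar), parameter = c(n = n, mu = mu),
         alternative = "angles concentrated at the specified mean direction",
         method = "V-test for circular non-uniformity",
         data.name = deparse(substitute(angles))),
    class = "htest")
}

#' Fraction of events locked to photostimulation
#'
#' Fraction of events whose nearest photostimulation trial lies within
#' \code{window} seconds — the definition behind "stimulation-correlated"
#' event onsets.
#'
#' @param event_times event times (s).
#' @param stim_times photostimulation onset times (s).
#' @param window half-width of the locked bin (s).
#' @return Fraction in [0, 1]; NA when there are no events.
#' @export
triggeredFraction <- function(event_times, stim_times, window = 0.5) {
  if (!length(event_times)) return(NA_real_)
  stim_times <- sort(stim_times)
  d <- vapply(event_times,
              function(e) min(abs(e - stim_times)), numeric(1))
  mean(d <= window)
}
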