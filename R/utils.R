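## Small internal helpers shared across modules.

#' @importFrom methods is new validObject slot
#' @importFrom stats rnorm runif rpois sd qt pnorm cor aov t.test TukeyHSD
#'   plogis median filter complete.cases
NULL

.isScalarNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

.assertScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!.isScalarNumber(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

## Euclidean distances between one point and rows of a 2-column matrix.
.distTo <- function(xy, p) {
  sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)
}

## Pairwise distance matrix between two point sets (rows are points).
.crossDist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}

## Centered moving average used for light smoothing before peak bookkeeping.
## Window is forced to an odd number of frames; edges use shrunken windows.
.movingAverage <- function(x, window) {
  if (window <= 1L) return(x)
  half <- floor(window / 2)
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

## Two-sided t confidence interval half-width; NA when n < 2 or sd is NA.
.ciHalfWidth <- function(x, conf = 0.95) {
  n <- sum(is.finite(x))
  if (n < 2L) return(NA_real_)
  s <- stats::sd(x[is.finite(x)])
  stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
}

## Normalize a 2-vector to unit length.
.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("direction vector must be non-zero", call. = FALSE)
  v / nv
}

.wrapAngle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}
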