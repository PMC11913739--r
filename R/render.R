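## Rasterization of simulated experiments into pixel frame stacks. Used by the
## pixel-domain operations (annulus neuropil, target-disk extraction,
## trial-centered frame averages) and their tests.

## Pixel-center coordinates (um) of a [ny, nx] grid in column-major order,
## matching R array layout. The FOV origin is the lower-left corner.
.pixelCoords <- function(ny, nx, pixel_size) {
  col <- rep(seq_len(nx), each = ny)
  row <- rep(seq_len(ny), times = nx)
  list(x = (col - 0.5) * pixel_size, y = (row - 0.5) * pixel_size)
}

#' Render a simulated experiment into a pixel frame stack
#'
#' Rasterizes selected frames of a simulated experiment: every pixel carries
#' the bulk (neuropil) seizure-recruitment field implied by the ground-truth
#' wavefront geometry plus Gaussian pixel noise, and pixels inside a soma show
#' that neuron's own trace. Intensities are in baseline-normalized units
#' (quiescent tissue is about 1).
#'
#' @param expt a simulated \code{\linkS4class{SeizureExperiment}}.
#' @param frames integer indices of the frames to render.
#' @param pixel_size pixel pitch in um.
#' @return A list with \code{stack} (array ny x nx x frames), \code{times}
#'   (frame times, s), \code{pixel_size} and \code{frames}.
#' @examples
#' expt <- simulateExperiment(simConfig(n_neurons = 10, fov = c(200, 200),
#'                                      duration = 20, seed = 2))
#' rf <- renderFrames(expt, frames = 1:3, pixel_size = 8)
#' dim(rf$stack)
#' @export
renderFrames <- function(expt, frames, pixel_size = 4) {
  stopifnot(is(expt, "SeizureExperiment"))
  gt <- groundTruth(expt)
  if (!length(gt))
    stop("renderFrames needs a simulated experiment with ground truth")
  config <- S4Vectors::metadata(expt)$config
  tt <- frameTimes(expt)[frames]
  nx <- as.integer(ceiling(config@fov[1] / pixel_size))
  ny <- as.integer(ceiling(config@fov[2] / pixel_size))
  pc <- .pixelCoords(ny, nx, pixel_size)
  np <- nx * ny

  ## neuropil recruitment field from the ground-truth wavefront geometry
  s_px <- .projCoord(cbind(pc$x, pc$y), config)
  field <- matrix(0, np, length(tt))
  szs <- as.data.frame(seizures(expt))
  tau <- config@transient_tau
  for (k in seq_len(nrow(szs))) {
    if (is.na(szs$onset[k])) next
    rec_px <- szs$onset[k] + s_px / config@wavefront_speed
    inwin <- which(tt >= szs$onset[k] & tt <= szs$offset[k])
    for (j in inwin) {
      field[, j] <- field[, j] + config@seizure_plateau *
        stats::plogis((tt[j] - rec_px) / config@recruit_rise_tau)
    }
    post <- which(tt > szs$offset[k] & tt <= szs$offset[k] + 6 * tau)
    if (length(post)) {
      vend <- config@seizure_plateau *
        stats::plogis((szs$offset[k] - rec_px) / config@recruit_rise_tau)
      for (j in post)
        field[, j] <- field[, j] + vend * exp(-(tt[j] - szs$offset[k]) / tau)
    }
  }

  m <- 1 + field + matrix(rnorm(np * length(tt), 0, config@noise_sd),
                          np, length(tt))

  ## paint somata with each neuron's own trace (baseline-normalized)
  rd <- rois(expt)
  raw <- SummarizedExperiment::assay(expt, "fluorescence")[, frames,
                                                           drop = FALSE]
  sigs <- raw / rd$f0  # 1 + signal + noise
  for (i in seq_len(nrow(rd))) {
    d <- sqrt((pc$x - rd$x[i])^2 + (pc$y - rd$y[i])^2)
    px <- which(d <= rd$radius[i])
    if (length(px))
      m[px, ] <- matrix(sigs[i, ], length(px), length(tt), byrow = TRUE)
  }
  list(stack = array(m, c(ny, nx, length(tt))), times = tt,
       pixel_size = pixel_size, frames = frames)
}

#' Pixel masks for simulated ROIs
#'
#' Linear pixel indices (column-major, grid as in \code{\link{renderFrames}})
#' of each neuron's soma disk.
#'
#' @param expt a simulated \code{\linkS4class{SeizureExperiment}}.
#' @param pixel_size pixel pitch in um.
#' @return A list of integer vectors, one per neuron.
#' @export
roiMasks <- function(expt, pixel_size = 4) {
  config <- S4Vectors::metadata(expt)$config
  nx <- as.integer(ceiling(config@fov[1] / pixel_size))
  ny <- as.integer(ceiling(config@fov[2] / pixel_size))
  pc <- .pixelCoords(ny, nx, pixel_size)
  rd <- rois(expt)
  lapply(seq_len(nrow(rd)), function(i) {
    which(sqrt((pc$x - rd$x[i])^2 + (pc$y - rd$y[i])^2) <= rd$radius[i])
  })
}
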