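## Plain-text (CSV) interchange of the experiment tables: ROI, trial, seizure
## and wavefront-annotation tables. Trace matrices are in-memory objects; the
## simulator regenerates them from a config and seed.

#' Write experiment tables to CSV
#'
#' Writes \code{rois.csv}, \code{trials.csv}, \code{seizures.csv} and
#' \code{front_lines.csv} into a directory.
#'
#' @param expt a \code{\linkS4class{SeizureExperiment}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeExperimentTables <- function(expt, dir) {
  stopifnot(is(expt, "SeizureExperiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("rois.csv", "trials.csv", "seizures.csv",
                            "front_lines.csv"))
  utils::write.csv(rois(expt), paths[1L], row.names = FALSE)
  utils::write.csv(as.data.frame(trials(expt)), paths[2L], row.names = FALSE)
  utils::write.csv(as.data.frame(seizures(expt)), paths[3L],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(frontLines(expt)), paths[4L],
                   row.names = FALSE)
  invisible(paths)
}

#' Read a trial table from CSV
#'
#' @param path CSV with at least \code{onset} and \code{offset} columns (s).
#' @return data.frame of trials, validated.
#' @export
readTrialTable <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("onset", "offset") %in% names(x)))
    stop("trial table needs 'onset' and 'offset' columns")
  if (any(x$onset >= x$offset))
    stop("trial onsets must precede offsets")
  x
}

#' Read a seizure table from CSV
#'
#' @param path CSV with \code{onset} and \code{offset} columns (s); onset may
#'   be NA for a seizure ongoing at recording start.
#' @return data.frame of seizures, validated for non-overlap.
#' @export
readSeizureTable <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("onset", "offset") %in% names(x)))
    stop("seizure table needs 'onset' and 'offset' columns")
  on <- ifelse(is.na(x$onset), -Inf, x$onset)
  ord <- order(on)
  if (any(utils::head(x$offset[ord], -1L) > on[ord][-1L]))
    stop("seizure intervals must not overlap")
  x
}

#' Read wavefront annotations from CSV
#'
#' @param path CSV with columns \code{trial_id, x1, y1, x2, y2, ref_x, ref_y}
#'   (um).
#' @return A named list of \code{\linkS4class{FrontLine}} objects keyed by
#'   trial id.
#' @export
readFrontLines <- function(path) {
  x <- utils::read.csv(path)
  need <- c("trial_id", "x1", "y1", "x2", "y2", "ref_x", "ref_y")
  if (!all(need %in% names(x)))
    stop("front-line table needs columns ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(x)), function(i)
    frontLine(c(x$x1[i], x$y1[i]), c(x$x2[i], x$y2[i]),
              ref = c(x$ref_x[i], x$ref_y[i])))
  names(out) <- x$trial_id
  out
}
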