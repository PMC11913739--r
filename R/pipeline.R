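## End-to-end orchestration: simulate (or take) an experiment, run every
## analysis stage, and return the figure-style summary tables plus a
## ground-truth recovery report for synthetic data.

#' Run the full analysis pipeline
#'
#' Runs every stage of the analysis on an experiment: dF/F normalization,
#' trial-state labelling, photostimulation response matrices and
#' baseline-referenced z-scores, state-wise activity rates and response
#' summaries, the photostimulation-seizure phase test, wavefront
#' distance profiles of target excitability, proximal/distal non-target
#' responses, the influence-versus-distance profile, and (for simulated
#' input) recruitment-time recovery against ground truth. All parameters
#' default to the package-wide conventions (500 ms response windows, 65%
#' recruitment threshold, 20 um target exclusion zones, 40 um rolling bins,
#' 1 s phase bins) and are recorded in the returned manifest.
#'
#' @param x a \code{\linkS4class{SimConfig}} (simulated first) or a
#'   \code{\linkS4class{SeizureExperiment}}.
#' @param recruit_frac recruitment threshold fraction.
#' @param bin_width rolling-bin width (um) for the target response profile.
#' @param phase_bin phase bin width (s).
#' @param exclusion_radius non-target exclusion radius (um).
#' @param influence_breaks distance bin edges (um) for the influence profile.
#' @return A list of stage outputs: \code{experiment}, \code{responses}
#'   (trials x neurons), \code{zscores}, \code{state_summary},
#'   \code{activity_rates}, \code{phase} (htest or NULL),
#'   \code{triggered_fraction}, \code{wavefront_profile},
#'   \code{nontarget_by_zone}, \code{influence_profile}, \code{recovery},
#'   \code{manifest}.
#' @examples
#' rep <- runPipeline(simConfig(n_neurons = 40, duration = 120,
#'                              injection_time = 40, seizure_times = 80,
#'                              seizure_duration = 10, seed = 3))
#' names(rep)
#' @export
runPipeline <- function(x, recruit_frac = 0.65, bin_width = 40,
                        phase_bin = 1, exclusion_radius = 20,
                        influence_breaks = seq(0, 400, by = 40)) {
  expt <- if (is(x, "SimConfig")) simulateExperiment(x) else x
  stopifnot(is(expt, "SeizureExperiment"))
  if (!"dff" %in% SummarizedExperiment::assayNames(expt))
    expt <- addDff(expt)

  trl <- as.data.frame(trials(expt))
  szs <- as.data.frame(seizures(expt))
  rd <- rois(expt)
  tt <- frameTimes(expt)
  fr <- frameRate(expt)
  tgt <- which(rd$is_target)

  resp <- responseMatrix(expt)
  base_rows <- which(trl$state == "baseline")
  zsc <- if (length(base_rows) >= 2L) zscoreMatrix(resp, base_rows) else
    resp * NA_real_

  ## state-wise response summary for targets (mean response, CV, pre-stim)
  dff <- SummarizedExperiment::assay(expt, "dff")
  pre_lv <- vapply(seq_len(nrow(trl)), function(k) {
    mean(vapply(tgt, function(i)
      prestimLevel(dff[i, ], tt, trl$onset[k],
                   excluded = excludedFrames(expt)), numeric(1)),
      na.rm = TRUE)
  }, numeric(1))
  grp <- ifelse(!is.na(trl$substate), trl$substate, trl$state)
  state_summary <- do.call(rbind, lapply(split(seq_len(nrow(trl)), grp),
    function(idx) {
      rmat <- resp[idx, tgt, drop = FALSE]
      data.frame(state = grp[idx[1L]], n_trials = length(idx),
                 mean_response = mean(rmat, na.rm = TRUE),
                 mean_cv = mean(apply(rmat, 2L, responseCV), na.rm = TRUE),
                 mean_zscore = mean(zsc[idx, tgt], na.rm = TRUE),
                 mean_prestim = mean(pre_lv[idx], na.rm = TRUE))
    }))
  rownames(state_summary) <- NULL

  ## state-wise activity rates from the deconvolved signal
  activity_rates <- NULL
  if ("deconvolved" %in% SummarizedExperiment::assayNames(expt)) {
    dec <- SummarizedExperiment::assay(expt, "deconvolved")
    cfg <- S4Vectors::metadata(expt)$config
    inj <- if (!is.null(cfg)) cfg@injection_time else 0
    ict <- rep(FALSE, length(tt))
    for (k in seq_len(nrow(szs))) {
      on <- if (is.na(szs$onset[k])) -Inf else szs$onset[k]
      ict <- ict | (tt >= on & tt <= szs$offset[k])
    }
    fsets <- list(baseline = tt < inj & !excludedFrames(expt),
                  interictal = tt >= inj & !ict & !excludedFrames(expt),
                  ictal = ict & !excludedFrames(expt))
    activity_rates <- do.call(rbind, lapply(names(fsets), function(s) {
      if (!any(fsets[[s]])) return(NULL)
      data.frame(state = s, roi_id = rd$roi_id,
                 rate = activityRate(dec, fr, frames = fsets[[s]]))
    }))
  }

  ## phase locking of seizure onsets to the stimulation grid
  phase <- NULL
  trig_frac <- NA_real_
  ev <- szs$onset[!is.na(szs$onset)]
  if (length(ev) >= 1L && nrow(trl) >= 2L) {
    ps <- eventPhases(ev, trl$onset, bin = phase_bin)
    if (ps@n_events >= 1L) phase <- vTest(ps, mu = 0)
    trig_frac <- triggeredFraction(ev, trl$onset)
  }

  ## target excitability versus wavefront distance
  fls <- as.data.frame(frontLines(expt))
  wavefront_profile <- NULL
  nontarget_by_zone <- NULL
  if (nrow(fls)) {
    dists <- zvals <- numeric(0)
    nt_tab <- selectNontargets(rd, exclusion_radius = exclusion_radius)
    nt_idx <- match(nt_tab$roi_id, rd$roi_id)
    nt_resp <- nt_dist <- numeric(0)
    for (r in seq_len(nrow(fls))) {
      k <- match(fls$trial_id[r], trl$trial_id)
      fl <- frontLine(c(fls$x1[r], fls$y1[r]), c(fls$x2[r], fls$y2[r]),
                      ref = c(fls$ref_x[r], fls$ref_y[r]))
      d_t <- distanceToFront(cbind(rd$x[tgt], rd$y[tgt]), fl)
      dists <- c(dists, d_t)
      zvals <- c(zvals, zsc[k, tgt])
      if (length(nt_idx)) {
        nt_dist <- c(nt_dist, distanceToFront(cbind(nt_tab$x, nt_tab$y), fl))
        nt_resp <- c(nt_resp, resp[k, nt_idx])
      }
    }
    wavefront_profile <- rollingProfile(zvals, dists, bin_width = bin_width)
    if (length(nt_resp)) {
      zone <- classifyProximalDistal(nt_dist)
      nontarget_by_zone <- data.frame(zone = levels(zone),
        mean_response = tapply(nt_resp, zone, mean, na.rm = TRUE),
        n = as.integer(table(zone)))
      rownames(nontarget_by_zone) <- NULL
    }
  }

  ## influence profile on interictal trials
  influence_profile <- NULL
  it <- which(trl$state == "interictal")
  nt_tab <- selectNontargets(rd, exclusion_radius = exclusion_radius)
  nt_idx <- match(nt_tab$roi_id, rd$roi_id)
  if (length(it) >= 3L && length(nt_idx) >= 2L) {
    im <- influenceMetric(resp[it, nt_idx, drop = FALSE])
    influence_profile <- influenceVsDistance(
      im$influence, cbind(nt_tab$x, nt_tab$y),
      cbind(rd$x[tgt], rd$y[tgt]), breaks = influence_breaks)
  }

  ## ground-truth recovery for synthetic input
  recovery <- NULL
  gt <- groundTruth(expt)
  if (length(gt) && nrow(szs)) {
    rows <- list()
    for (k in seq_len(nrow(szs))) {
      if (is.na(szs$onset[k])) next
      for (i in seq_len(nrow(rd))) {
        truth <- gt$recruitment_time[i, k]
        if (is.na(truth)) next
        al <- try(alignToSeizure(dff[i, ], tt, szs$onset[k],
                                 excluded = excludedFrames(expt)),
                  silent = TRUE)
        if (inherits(al, "try-error")) next
        dl <- recruitmentDelay(al, tt, szs$onset[k], szs$offset[k],
                               frac = recruit_frac,
                               excluded = excludedFrames(expt))
        rows[[length(rows) + 1L]] <- data.frame(
          seizure_id = szs$seizure_id[k], roi_id = rd$roi_id[i],
          measured_delay = dl, true_delay = truth - szs$onset[k])
      }
    }
    if (length(rows)) {
      recovery <- do.call(rbind, rows)
      attr(recovery, "rmse_frames") <-
        sqrt(mean((recovery$measured_delay - recovery$true_delay)^2,
                  na.rm = TRUE)) * fr
    }
  }

  manifest <- list(
    parameters = list(recruit_frac = recruit_frac, bin_width = bin_width,
                      phase_bin = phase_bin,
                      exclusion_radius = exclusion_radius,
                      influence_breaks = influence_breaks,
                      response_window = 0.5, decay_frac = 0.63,
                      overlap_max = 0.05, annulus = c(20, 100),
                      subperiod_window = 30),
    seed = if (is(x, "SimConfig")) x@seed else NA_integer_,
    package_version = as.character(utils::packageVersion("penumbra")))

  list(experiment = expt, responses = resp, zscores = zsc,
       state_summary = state_summary, activity_rates = activity_rates,
       phase = phase, triggered_fraction = trig_frac,
       wavefront_profile = wavefront_profile,
       nontarget_by_zone = nontarget_by_zone,
       influence_profile = influence_profile, recovery = recovery,
       manifest = manifest)
}

#' Standard hypothesis tests between state groups
#'
#' Delegates to the standard tests used for state comparisons: Welch/paired t
#' test for two groups, one-way ANOVA with Tukey post-hoc comparisons for
#' three or more. Bespoke quantities are computed upstream; this is plain
#' inference on grouped values.
#'
#' @param values numeric vector.
#' @param groups grouping factor/character, same length.
#' @param paired use a paired t test (two groups of equal length only).
#' @return data.frame with one row per comparison: \code{comparison},
#'   \code{statistic}, \code{p}, \code{n1}, \code{n2}, \code{test}. Degenerate
#'   groups (n < 2) are skipped with a warning.
#' @examples
#' stateComparisons(c(rnorm(10), rnorm(10, 5)), rep(c("a", "b"), each = 10))
#' @export
stateComparisons <- function(values, groups, paired = FALSE) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(as.character(groups[ok]))
  n_per <- table(groups)
  if (any(n_per < 2L)) {
    warning("dropping degenerate group(s): ",
            paste(names(n_per)[n_per < 2L], collapse = ", "))
    keep <- groups %in% names(n_per)[n_per >= 2L]
    values <- values[keep]
    groups <- droplevels(groups[keep])
    n_per <- table(groups)
  }
  if (nlevels(groups) < 2L)
    stop("need at least two groups with n >= 2")
  if (nlevels(groups) == 2L) {
    a <- values[groups == levels(groups)[1L]]
    b <- values[groups == levels(groups)[2L]]
    ht <- stats::t.test(a, b, paired = paired)
    return(data.frame(
      comparison = paste(levels(groups), collapse = " vs "),
      statistic = unname(ht$statistic), p = ht$p.value,
      n1 = length(a), n2 = length(b),
      test = if (paired) "paired t" else "t"))
  }
  fit <- stats::aov(values ~ groups)
  p_f <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tuk <- stats::TukeyHSD(fit)$groups
  out <- data.frame(comparison = rownames(tuk), statistic = tuk[, "diff"],
                    p = tuk[, "p adj"],
                    n1 = NA_integer_, n2 = NA_integer_, test = "Tukey HSD")
  for (i in seq_len(nrow(out))) {
    gg <- strsplit(out$comparison[i], "-", fixed = TRUE)[[1L]]
    out$n1[i] <- n_per[gg[1L]]
    out$n2[i] <- n_per[gg[2L]]
  }
  rbind(data.frame(comparison = "overall (one-way ANOVA)",
                   statistic = summary(fit)[[1L]][["F value"]][1L],
                   p = p_f, n1 = length(values), n2 = NA_integer_,
                   test = "ANOVA F"),
        out)
}

#' Pre-stimulation neuropil signal versus wavefront distance
#'
#' For every neuron, measures the annulus (20-100 um) neuropil level in a
#' short window (default 0-250 ms) before each photostimulation trial on
#' rendered frames, z-scores each neuron's ictal-trial measures against its
#' baseline-trial distribution, and bins them by the neuron's signed
#' distance to the trial's annotated wavefront in 20 um rolling bins — the
#' neuropil counterpart of the target excitability profile.
#'
#' @param expt a simulated \code{\linkS4class{SeizureExperiment}} with
#'   wavefront annotations.
#' @param prestim_window window length (s) before trial onset.
#' @param bin_width,step rolling-bin geometry (um).
#' @param pixel_size rendering pitch (um).
#' @param max_dist analysis radius (um); annotated distances beyond it are
#'   dropped.
#' @return A rolling-profile data.frame (see \code{\link{rollingProfile}}).
#' @export
neuropilProfile <- function(expt, prestim_window = 0.25, bin_width = 20,
                            step = 5, pixel_size = 8, max_dist = 400) {
  stopifnot(is(expt, "SeizureExperiment"))
  trl <- as.data.frame(trials(expt))
  fls <- as.data.frame(frontLines(expt))
  if (!nrow(fls)) stop("no wavefront annotations")
  rd <- rois(expt)
  tt <- frameTimes(expt)
  base_id <- trl$trial_id[trl$state == "baseline"]
  use <- rbind(data.frame(trial_id = base_id, ictal = FALSE),
               data.frame(trial_id = fls$trial_id, ictal = TRUE))
  frame_sets <- lapply(use$trial_id, function(id) {
    on <- trl$onset[match(id, trl$trial_id)]
    which(tt >= on - prestim_window & tt < on & !excludedFrames(expt))
  })
  frames <- sort(unique(unlist(frame_sets)))
  rf <- renderFrames(expt, frames, pixel_size = pixel_size)
  ## per-neuron annulus trace over the rendered frames
  ann <- t(vapply(seq_len(nrow(rd)), function(i) {
    annulusNeuropil(rf$stack, c(rd$x[i], rd$y[i]), pixel_size = pixel_size)
  }, numeric(length(frames))))
  lev <- vapply(frame_sets, function(fs) {
    if (!length(fs)) return(rep(NA_real_, nrow(rd)))
    rowMeans(ann[, match(fs, frames), drop = FALSE])
  }, numeric(nrow(rd)))              # neurons x used-trials
  zb <- lev[, !use$ictal, drop = FALSE]
  dists <- zvals <- numeric(0)
  for (r in seq_len(nrow(fls))) {
    col <- which(use$ictal)[r]
    fl <- frontLine(c(fls$x1[r], fls$y1[r]), c(fls$x2[r], fls$y2[r]),
                    c(fls$ref_x[r], fls$ref_y[r]))
    d <- distanceToFront(cbind(rd$x, rd$y), fl)
    z <- vapply(seq_len(nrow(rd)), function(i)
      zscoreToBaseline(lev[i, col], zb[i, ]), numeric(1))
    keep <- abs(d) <= max_dist
    dists <- c(dists, d[keep])
    zvals <- c(zvals, z[keep])
  }
  rollingProfile(zvals, dists, bin_width = bin_width, step = step)
}
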