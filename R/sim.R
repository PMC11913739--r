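## Synthetic all-optical seizure experiments with ground truth.
##
## The generative model, in trace (dF/F) units:
##   signal = spontaneous transients (Poisson impulses convolved with an
##            exponential kernel, decay transient_tau)
##          + seizure recruitment (sigmoidal rise to seizure_plateau at the
##            neuron's ground-truth recruitment time, exponential decay after
##            seizure offset)
##          + photostimulation-evoked transients on targets (amplitude =
##            stim_gain_interictal x gain_vs_front_distance(signed distance)
##            x (1 + shared per-trial fluctuation))
##          + coupling-propagated responses on non-targets
##          + a common additive network response on every neuron, scaled by
##            the same shared per-trial fluctuation
##   post-ictal frames are scaled by postictal_suppression;
##   raw fluorescence = f0 x (1 + signal + Gaussian noise), plus a large
##   photostimulation artifact on the frames of each trial.

## Projected coordinate along the propagation axis, zeroed at the FOV corner
## the wavefront enters first (so the onset line is tangent to the FOV).
.projCoord <- function(xy, config) {
  u <- config@wavefront_direction
  corners <- rbind(c(0, 0), c(config@fov[1], 0), c(0, config@fov[2]),
                   config@fov)
  smin <- min(corners %*% u)
  drop(xy %*% u) - smin
}

#' Simulate a complete all-optical seizure experiment
#'
#' Generates ROIs, fluorescence and deconvolved trace matrices, a
#' photostimulation trial table, seizure intervals with per-trial wavefront
#' annotations, an LFP proxy channel, and the full ground truth, following the
#' generative model described in the package vignette. Identical
#' configurations (including the seed) give bit-identical experiments.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return A \code{\linkS4class{SeizureExperiment}} with assays
#'   \code{"fluorescence"} (raw, a.u.) and \code{"deconvolved"} (a.u.), and
#'   ground truth accessible via \code{\link{groundTruth}}.
#' @examples
#' expt <- simulateExperiment(simConfig(n_neurons = 20, duration = 80,
#'                                      injection_time = 20,
#'                                      seizure_times = 50,
#'                                      seizure_duration = 10, seed = 1))
#' expt
#' @export
simulateExperiment <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)

  fr <- config@frame_rate
  nF <- as.integer(floor(config@duration * fr))
  tt <- (seq_len(nF) - 1L) / fr
  n <- config@n_neurons
  tau <- config@transient_tau
  v <- config@wavefront_speed

  ## --- ROI geometry and classes (RNG draws 1-3) ---------------------------
  xy <- cbind(x = runif(n, 0, config@fov[1]), y = runif(n, 0, config@fov[2]))
  n_inh <- round(config@frac_inhibitory * n)
  is_inh <- rep(FALSE, n)
  if (n_inh > 0) is_inh[sample.int(n, n_inh)] <- TRUE
  n_tgt <- round(config@frac_targets * n)
  exc <- which(!is_inh)
  is_tgt <- rep(FALSE, n)
  if (n_tgt > 0) is_tgt[sample(exc, min(n_tgt, length(exc)))] <- TRUE
  f0 <- runif(n, config@baseline_f0[1], config@baseline_f0[2])

  ## --- trial grid ---------------------------------------------------------
  onsets <- seq(config@stim_start,
                config@duration - config@stim_period, by = config@stim_period)
  trl <- data.frame(trial_id = seq_along(onsets), onset = onsets,
                    offset = onsets + config@stim_duration,
                    modality = config@stim_modality)
  nT <- nrow(trl)

  ## --- seizures: scheduled + stimulation-triggered (RNG draws 4) ----------
  sz_on <- config@seizure_times
  if (any(sz_on + config@seizure_duration > config@duration))
    stop("scheduled seizures extend beyond the recording")
  trig_u <- runif(nT)
  trig_jit <- rnorm(nT, 0, config@trigger_jitter_sd)
  triggered_by <- rep(NA_integer_, length(sz_on))
  if (config@trigger_prob > 0) {
    for (k in seq_len(nT)) {
      t0 <- trl$onset[k]
      if (t0 < config@injection_time) next
      if (any(t0 >= sz_on & t0 <= sz_on + config@seizure_duration)) next
      if (trig_u[k] >= config@trigger_prob) next
      cand <- t0 + trig_jit[k]
      if (cand < config@injection_time) next
      if (cand + config@seizure_duration > config@duration) next
      ## keep seizures separated by at least 2 s
      ok <- all(cand > sz_on + config@seizure_duration + 2 |
                cand + config@seizure_duration + 2 < sz_on)
      if (!ok) next
      sz_on <- c(sz_on, cand)
      triggered_by <- c(triggered_by, k)
      ord <- order(sz_on)
      sz_on <- sz_on[ord]
      triggered_by <- triggered_by[ord]
    }
  }
  szs <- data.frame(seizure_id = seq_along(sz_on), onset = sz_on,
                    offset = sz_on + config@seizure_duration,
                    triggered_by = triggered_by)
  nS <- nrow(szs)

  ## --- ground-truth recruitment times -------------------------------------
  s_proj <- .projCoord(xy, config)
  rec <- matrix(NA_real_, n, max(nS, 0))
  if (nS > 0) {
    for (k in seq_len(nS)) {
      r <- szs$onset[k] + s_proj / v
      r[r > szs$offset[k]] <- NA_real_
      rec[, k] <- r
    }
  }

  ## --- trial states -------------------------------------------------------
  st <- classifyTrialState(trl, szs, injection_time = config@injection_time)
  trl$state <- st$state
  trl$substate <- st$substate

  ## --- shared per-trial fluctuation and evoked amplitudes (RNG draw 5) ----
  eps <- rnorm(nT, 0, config@shared_fluctuation_sd)
  tgt_idx <- which(is_tgt)
  gain <- matrix(NA_real_, nT, length(tgt_idx))
  amp <- matrix(0, nT, length(tgt_idx))
  for (k in seq_len(nT)) {
    mult <- rep(1, length(tgt_idx))
    insz <- which(!is.na(szs$onset) & trl$onset[k] >= szs$onset &
                  trl$onset[k] <= szs$offset)
    if (length(insz)) {
      kk <- insz[1]
      d_signed <- s_proj[tgt_idx] - v * (trl$onset[k] - szs$onset[kk])
      mult <- config@gain_vs_front_distance(d_signed)
      gain[k, ] <- mult
    }
    amp[k, ] <- config@stim_gain_interictal * mult * (1 + eps[k])
  }

  ## --- coupling matrix ----------------------------------------------------
  ntg_idx <- which(!is_tgt)
  W <- matrix(0, length(tgt_idx), length(ntg_idx))
  if (length(tgt_idx) && length(ntg_idx) && config@coupling_weight != 0) {
    D <- .crossDist(xy[tgt_idx, , drop = FALSE], xy[ntg_idx, , drop = FALSE])
    W <- matrix(config@coupling_kernel(D, config@coupling_weight),
                nrow = length(tgt_idx))
  }

  ## --- impulse matrix: spontaneous events + evoked + coupled (RNG draw 6) -
  imp <- matrix(0, n, nF)
  deconv <- matrix(0, n, nF)
  for (i in seq_len(n)) {
    n_ev <- rpois(1, config@transient_rate * config@duration)
    if (n_ev == 0) next
    ev <- runif(n_ev, 0, config@duration)
    if (nS > 0) {
      keep <- rep(TRUE, n_ev)
      for (k in seq_len(nS)) {
        if (is.na(rec[i, k])) next
        keep <- keep & !(ev >= rec[i, k] & ev <= szs$offset[k])
      }
      ev <- ev[keep]
    }
    if (!length(ev)) next
    idx <- pmin(nF, floor(ev * fr) + 1L)
    for (j in idx) imp[i, j] <- imp[i, j] + config@transient_amp
  }
  deconv <- imp

  off_frame <- pmin(nF, floor(trl$offset * fr) + 1L)
  for (k in seq_len(nT)) {
    jf <- off_frame[k]
    if (length(tgt_idx))
      imp[tgt_idx, jf] <- imp[tgt_idx, jf] + amp[k, ]
    if (length(ntg_idx) && any(W != 0))
      imp[ntg_idx, jf] <- imp[ntg_idx, jf] + drop(crossprod(W, amp[k, ]))
    ## common network response to ensemble stimulation, on every neuron
    if (config@stim_global_amp != 0)
      imp[, jf] <- imp[, jf] + config@stim_global_amp * (1 + eps[k])
  }

  ## exponential kernel via a recursive (AR1) filter, one pass per neuron
  alpha <- exp(-1 / (fr * tau))
  sig <- t(apply(imp, 1L, function(r)
    as.numeric(stats::filter(r, alpha, method = "recursive"))))

  ## --- seizure recruitment component --------------------------------------
  if (nS > 0) {
    for (k in seq_len(nS)) {
      win <- which(tt >= szs$onset[k] & tt <= szs$offset[k])
      ri <- which(!is.na(rec[, k]))
      if (length(win) && length(ri)) {
        dt <- outer(rec[ri, k], tt[win], function(r, t)
          stats::plogis((t - r) / config@recruit_rise_tau))
        sig[ri, win] <- sig[ri, win] + config@seizure_plateau * dt
        ## ictal drive in the deconvolved channel sustains the plateau
        drive <- config@seizure_plateau / (tau * fr)
        dmask <- outer(rec[ri, k], tt[win], function(r, t) t >= r)
        deconv[ri, win] <- deconv[ri, win] + drive * dmask
        ## decay back to baseline after offset
        vend <- config@seizure_plateau *
          stats::plogis((szs$offset[k] - rec[ri, k]) / config@recruit_rise_tau)
        post <- which(tt > szs$offset[k] & tt <= szs$offset[k] + 6 * tau)
        if (length(post)) {
          dec <- outer(vend, exp(-(tt[post] - szs$offset[k]) / tau))
          sig[ri, post] <- sig[ri, post] + dec
        }
      }
      ## post-ictal multiplicative suppression
      pidx <- which(tt > szs$offset[k] &
                    tt <= szs$offset[k] + config@postictal_window)
      if (length(pidx) && config@postictal_suppression < 1) {
        sig[, pidx] <- sig[, pidx] * config@postictal_suppression
        deconv[, pidx] <- deconv[, pidx] * config@postictal_suppression
      }
    }
  }

  ## --- raw fluorescence (RNG draw 7) ---------------------------------------
  raw <- sig + matrix(rnorm(n * nF, 0, config@noise_sd), n, nF)
  raw <- f0 * (1 + raw)

  ## --- frame exclusion and stimulation artifact ----------------------------
  if (config@stim_modality == "widefield") {
    trl$shutter_deploy <- trl$onset - 0.05
    trl$shutter_release <- trl$offset + 0.05
    excl_tab <- data.frame(onset = trl$shutter_deploy,
                           offset = trl$shutter_release)
  } else {
    excl_tab <- trl[, c("onset", "offset")]
  }
  mapped <- mapTrialsToFrames(excl_tab, tt)
  excluded <- mapped$excluded
  trl$onset_frame <- mapped$trials$onset_frame
  trl$offset_frame <- mapped$trials$offset_frame
  if (any(excluded)) {
    if (config@stim_modality == "widefield") {
      raw[, excluded] <- raw[, excluded] * 0.02  # PMT shutters closed
    } else {
      raw[, excluded] <- raw[, excluded] + 3 * f0  # stimulation laser artifact
    }
  }

  ## --- LFP proxy (RNG draw 8) ----------------------------------------------
  lfp_rate <- 100
  lt <- seq(0, config@duration - 1 / lfp_rate, by = 1 / lfp_rate)
  lfp <- rnorm(length(lt), 0, 0.2)
  if (nS > 0) {
    for (k in seq_len(nS)) {
      w <- which(lt >= szs$onset[k] & lt <= szs$offset[k])
      lfp[w] <- lfp[w] + 3 * sin(2 * pi * 6 * lt[w]) +
        rnorm(length(w), 0, 0.5)
    }
  }

  ## --- wavefront annotations for ictal trials ------------------------------
  fl <- data.frame(trial_id = integer(0), seizure_id = integer(0),
                   x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                   y2 = numeric(0), ref_x = numeric(0), ref_y = numeric(0))
  ict <- which(trl$state == "ictal")
  for (k in ict) {
    kk <- which(!is.na(szs$onset) & trl$onset[k] >= szs$onset &
                trl$onset[k] <= szs$offset)[1]
    if (is.na(kk)) next
    f <- frontLineAt(szs[kk, ], trl$onset[k], config)
    fl <- rbind(fl, data.frame(trial_id = trl$trial_id[k], seizure_id = kk,
                               x1 = f@p1[1], y1 = f@p1[2], x2 = f@p2[1],
                               y2 = f@p2[2], ref_x = f@ref[1],
                               ref_y = f@ref[2]))
  }

  ## --- assemble -------------------------------------------------------------
  rd <- S4Vectors::DataFrame(roi_id = seq_len(n), x = xy[, 1], y = xy[, 2],
                             radius = config@roi_radius, f0 = f0,
                             is_target = is_tgt, is_inhibitory = is_inh)
  cd <- S4Vectors::DataFrame(time = tt, excluded = excluded)
  dimnames(raw) <- dimnames(deconv) <-
    list(paste0("roi", seq_len(n)), NULL)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fluorescence = raw, deconvolved = deconv),
    rowData = rd, colData = cd,
    metadata = list(frame_rate = fr, config = config))
  gt <- list(recruitment_time = rec,
             gain = gain, evoked_amp = amp,
             coupling = W, shared = eps,
             triggered_trials = szs$triggered_by[!is.na(szs$triggered_by)],
             target_idx = tgt_idx, nontarget_idx = ntg_idx,
             proj_coord = s_proj,
             direction = config@wavefront_direction,
             speed = v)
  new("SeizureExperiment", se,
      trials = S4Vectors::DataFrame(trl),
      seizures = S4Vectors::DataFrame(szs),
      frontLines = S4Vectors::DataFrame(fl),
      lfp = list(time = lt, signal = lfp),
      groundTruth = gt)
}

#' Wavefront line of a simulated seizure at a given time
#'
#' Returns the simulator's analogue of a manual wavefront annotation: the
#' straight line perpendicular to the propagation direction, displaced
#' \code{wavefront_speed * (t - onset)} from the onset line, with the
#' penumbral reference point placed ahead of the front.
#'
#' @param seizure a one-row data.frame (or list) with \code{onset} and
#'   \code{offset} (s).
#' @param t time (s) at which to place the line; must lie within the seizure.
#' @param config the \code{\linkS4class{SimConfig}} that generated the
#'   experiment.
#' @return A \code{\linkS4class{FrontLine}}.
#' @examples
#' cfg <- simConfig()
#' frontLineAt(data.frame(onset = 10, offset = 30), t = 11, cfg)
#' @export
frontLineAt <- function(seizure, t, config) {
  stopifnot(is(config, "SimConfig"))
  if (is.na(seizure$onset))
    stop("no onset is defined for this seizure; its wavefront has no timing")
  if (t < seizure$onset || t > seizure$offset)
    stop("t must lie within the seizure interval")
  u <- config@wavefront_direction
  w <- c(-u[2], u[1])
  m <- config@fov / 2
  corners <- rbind(c(0, 0), c(config@fov[1], 0), c(0, config@fov[2]),
                   config@fov)
  smin <- min(corners %*% u)
  s_f <- config@wavefront_speed * (t - seizure$onset)
  pc <- m + u * (s_f - (sum(m * u) - smin))
  half <- max(100, 0.6 * max(config@fov))
  frontLine(pc + w * half, pc - w * half, ref = pc + u * 50)
}
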