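#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration of a synthetic all-optical seizure experiment
#'
#' An object of class \code{SimConfig} holds every parameter of the synthetic
#' data generator: field-of-view geometry, neuron counts and class fractions,
#' GCaMP-like transient kinetics, seizure and wavefront dynamics,
#' photostimulation protocol and gain structure, target-to-non-target
#' coupling, and the random seed. Construct with \code{\link{simConfig}}.
#'
#' @slot fov numeric(2), field of view width and height in micrometers.
#' @slot n_neurons integer, number of segmented neurons.
#' @slot frac_targets fraction of neurons selected as photostimulation targets.
#' @slot frac_inhibitory fraction of neurons labelled inhibitory.
#' @slot frame_rate imaging frame rate in Hz.
#' @slot duration recording duration in seconds.
#' @slot injection_time time (s) of the convulsant injection; trials before it
#'   are baseline-state trials and no seizure may start before it.
#' @slot transient_rate,transient_amp,transient_tau Poisson rate (events/s),
#'   amplitude (dF/F) and exponential decay constant (s) of spontaneous
#'   calcium transients.
#' @slot noise_sd per-frame Gaussian noise SD in dF/F units.
#' @slot seizure_times,seizure_duration scheduled seizure onsets (s) and the
#'   common seizure duration (s).
#' @slot wavefront_speed,wavefront_direction propagation speed (um/s) and unit
#'   direction of the linear seizure wavefront.
#' @slot seizure_plateau ictal plateau amplitude (dF/F) after recruitment.
#' @slot recruit_rise_tau time constant (s) of the sigmoidal rise at
#'   recruitment.
#' @slot postictal_suppression,postictal_window multiplicative activity factor
#'   in (0, 1] applied for \code{postictal_window} seconds after each seizure.
#' @slot stim_start,stim_period,stim_duration photostimulation trial grid (s).
#' @slot stim_gain_interictal evoked response amplitude (dF/F) of a target
#'   outside seizures.
#' @slot gain_vs_front_distance function mapping signed distance to the
#'   wavefront (um, positive on the penumbral side) to a non-negative gain
#'   multiplier.
#' @slot coupling_weight,coupling_kernel magnitude w and signed kernel
#'   \code{function(d, w)} of target-to-non-target coupling over pairwise
#'   distance d (um).
#' @slot shared_fluctuation_sd SD of the per-trial fluctuation shared across
#'   neurons (drives correlated trial-to-trial variability): it multiplies
#'   every target's evoked amplitude and scales the additive global network
#'   response.
#' @slot stim_global_amp amplitude (dF/F) of the common additive response of
#'   every neuron to ensemble photostimulation (bulk network/neuropil drive);
#'   fluctuates with the shared per-trial factor.
#' @slot trigger_prob,trigger_jitter_sd probability that a post-injection
#'   trial initiates a seizure, and the SD (s) of the onset jitter around the
#'   trial time.
#' @slot baseline_f0 range of per-neuron baseline fluorescence (a.u.).
#' @slot roi_radius soma radius (um) used when rendering pixel masks.
#' @slot stim_modality "twophoton" or "widefield".
#' @slot seed integer random seed; identical seeds give identical experiments.
#' @seealso \code{\link{simConfig}}, \code{\link{simulateExperiment}}
#' @export
setClass("SimConfig",
  representation(
    fov = "numeric", n_neurons = "integer",
    frac_targets = "numeric", frac_inhibitory = "numeric",
    frame_rate = "numeric", duration = "numeric", injection_time = "numeric",
    transient_rate = "numeric", transient_amp = "numeric",
    transient_tau = "numeric", noise_sd = "numeric",
    seizure_times = "numeric", seizure_duration = "numeric",
    wavefront_speed = "numeric", wavefront_direction = "numeric",
    seizure_plateau = "numeric", recruit_rise_tau = "numeric",
    postictal_suppression = "numeric", postictal_window = "numeric",
    stim_start = "numeric", stim_period = "numeric", stim_duration = "numeric",
    stim_gain_interictal = "numeric",
    gain_vs_front_distance = "function",
    coupling_weight = "numeric", coupling_kernel = "function",
    shared_fluctuation_sd = "numeric", stim_global_amp = "numeric",
    trigger_prob = "numeric", trigger_jitter_sd = "numeric",
    baseline_f0 = "numeric", roi_radius = "numeric",
    stim_modality = "character", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  chk <- function(cond, m) if (!cond) msg <<- c(msg, m)
  chk(length(object@fov) == 2L && all(object@fov > 0),
      "fov must be two positive lengths (um)")
  chk(object@n_neurons >= 1L, "n_neurons must be >= 1")
  chk(object@frac_targets >= 0 && object@frac_targets <= 1,
      "frac_targets must lie in [0, 1]")
  chk(object@frac_inhibitory >= 0 && object@frac_inhibitory <= 1,
      "frac_inhibitory must lie in [0, 1]")
  chk(object@frame_rate > 0, "frame_rate must be > 0")
  chk(object@duration > 0, "duration must be > 0")
  chk(object@wavefront_speed > 0, "wavefront_speed must be > 0")
  chk(abs(sqrt(sum(object@wavefront_direction^2)) - 1) < 1e-8,
      "wavefront_direction must be a unit vector")
  chk(object@postictal_suppression > 0 && object@postictal_suppression <= 1,
      "postictal_suppression must lie in (0, 1]")
  chk(object@trigger_prob >= 0 && object@trigger_prob <= 1,
      "trigger_prob must lie in [0, 1]")
  chk(object@stim_modality %in% c("twophoton", "widefield"),
      "stim_modality must be 'twophoton' or 'widefield'")
  if (length(object@seizure_times)) {
    st <- sort(object@seizure_times)
    chk(all(diff(st) > object@seizure_duration),
        "scheduled seizure intervals must not overlap")
    chk(all(st >= object@injection_time),
        "seizures cannot start before injection_time")
  }
  g <- try(object@gain_vs_front_distance(c(-50, 50, 150, 250)), silent = TRUE)
  chk(!inherits(g, "try-error") && all(is.finite(g)) && all(g >= 0),
      "gain_vs_front_distance must return finite non-negative multipliers")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FrontLine
## ---------------------------------------------------------------------------

#' Linear approximation of the seizure wavefront
#'
#' A seizure wavefront annotation: an infinite line through two points at
#' least 100 um apart, plus a reference point marking the penumbral
#' (not-yet-recruited) side, which fixes the sign convention of
#' \code{\link{distanceToFront}} (positive towards the penumbra).
#'
#' @slot p1,p2 numeric(2), points (um) defining the line; at least 100 um
#'   apart.
#' @slot ref numeric(2), a point (um) strictly off the line on the penumbral
#'   side.
#' @export
setClass("FrontLine",
  representation(p1 = "numeric", p2 = "numeric", ref = "numeric"))

setValidity("FrontLine", function(object) {
  if (length(object@p1) != 2L || length(object@p2) != 2L ||
      length(object@ref) != 2L)
    return("p1, p2 and ref must be length-2 numeric coordinates (um)")
  v <- object@p2 - object@p1
  len <- sqrt(sum(v^2))
  if (len < 100)
    return("the two wavefront coordinates must be at least 100 um apart")
  nrm <- c(-v[2], v[1]) / len
  if (abs(sum((object@ref - object@p1) * nrm)) < 1e-9)
    return("the penumbral reference point must not lie on the wavefront line")
  TRUE
})

#' @rdname FrontLine-class
#' @param p1,p2 points (um) on the wavefront line, at least 100 um apart.
#' @param ref a point (um) on the penumbral side of the line.
#' @return A \code{FrontLine} object.
#' @examples
#' fl <- frontLine(c(0, 0), c(0, 150), ref = c(50, 0))
#' distanceToFront(cbind(50, 30), fl)
#' @export
frontLine <- function(p1, p2, ref) {
  new("FrontLine", p1 = as.numeric(p1), p2 = as.numeric(p2),
      ref = as.numeric(ref))
}

setMethod("show", "FrontLine", function(object) {
  cat(sprintf("FrontLine (%.1f, %.1f) -- (%.1f, %.1f), penumbra towards (%.1f, %.1f)\n",
              object@p1[1], object@p1[2], object@p2[1], object@p2[2],
              object@ref[1], object@ref[2]))
})

## ---------------------------------------------------------------------------
## PhaseSet
## ---------------------------------------------------------------------------

#' Event phases within the inter-photostimulation cycle
#'
#' Holds the binned phase angle of each event (e.g. seizure onset) relative to
#' the photostimulation cycle, as produced by \code{\link{eventPhases}}.
#' Angles live in [-pi, pi); the zero bin spans -bin/2 to +bin/2 seconds
#' around a photostimulation trial.
#'
#' @slot angles numeric, wrapped bin-center angles (radians).
#' @slot raw_angles numeric, unbinned angles for sensitivity analysis.
#' @slot bin_width phase bin width in seconds.
#' @slot stim_period representative (median) inter-stimulus period, seconds.
#' @slot n_events number of events retained.
#' @slot n_dropped number of events outside the stimulus span.
#' @seealso \code{\link{eventPhases}}, \code{\link{vTest}}
#' @export
setClass("PhaseSet",
  representation(angles = "numeric", raw_angles = "numeric",
                 bin_width = "numeric", stim_period = "numeric",
                 n_events = "integer", n_dropped = "integer"))

setValidity("PhaseSet", function(object) {
  if (object@n_events != length(object@angles))
    return("n_events must equal the number of angles")
  if (length(object@bin_width) == 1L && length(object@stim_period) == 1L &&
      object@bin_width > object@stim_period)
    return("bin_width cannot exceed the stimulation period")
  TRUE
})

setMethod("show", "PhaseSet", function(object) {
  cat(sprintf("PhaseSet: %d events (%d dropped), bin %.2g s, period %.2g s\n",
              object@n_events, object@n_dropped, object@bin_width,
              object@stim_period))
})

## ---------------------------------------------------------------------------
## SeizureExperiment
## ---------------------------------------------------------------------------

#' Container for an all-optical seizure experiment
#'
#' \code{SeizureExperiment} extends
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}}: rows are neurons
#' (the ROI table lives in \code{rowData}: centroid x/y in um, soma radius,
#' baseline fluorescence f0, \code{is_target}, \code{is_inhibitory}), columns
#' are imaging frames (\code{colData} holds the frame time in seconds and the
#' photostimulation-artifact exclusion flag). Assays are neurons x frames
#' matrices: at least \code{"fluorescence"} (raw, a.u.); the simulator also
#' provides \code{"deconvolved"}; \code{\link{addDff}} adds \code{"dff"}.
#'
#' @slot trials DataFrame of photostimulation trials (trial_id, onset, offset,
#'   modality, state, substate, onset_frame, offset_frame).
#' @slot seizures DataFrame of seizure intervals (seizure_id, onset, offset,
#'   triggered_by; onset is NA for a seizure ongoing at recording start).
#' @slot frontLines DataFrame of per-trial wavefront annotations (trial_id,
#'   seizure_id, x1, y1, x2, y2, ref_x, ref_y in um).
#' @slot lfp list with elements \code{time} and \code{signal}: the LFP proxy
#'   channel.
#' @slot groundTruth list of simulation ground truth (empty for real data):
#'   recruitment_time, gain, evoked_amp, coupling, shared, triggered_trials,
#'   and the wavefront geometry (origin, direction, speed).
#' @seealso \code{\link{simulateExperiment}}
#' @export
setClass("SeizureExperiment",
  contains = "SummarizedExperiment",
  representation(trials = "DataFrame", seizures = "DataFrame",
                 frontLines = "DataFrame", lfp = "list",
                 groundTruth = "list"))

setValidity("SeizureExperiment", function(object) {
  msg <- character(0)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time", "excluded") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'time' and 'excluded'")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("roi_id", "x", "y", "is_target", "is_inhibitory")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain", paste(need, collapse = ", ")))
  if (nrow(object@seizures)) {
    on <- object@seizures$onset
    off <- object@seizures$offset
    if (any(!is.na(on) & on >= off))
      msg <- c(msg, "seizure onset must precede offset")
  }
  if (nrow(object@trials) &&
      any(object@trials$onset >= object@trials$offset))
    msg <- c(msg, "trial onset must precede offset")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SeizureExperiment", function(object) {
  callNextMethod()
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("neurons: %d (%d targets, %d inhibitory)\n",
              nrow(object), sum(rd$is_target), sum(rd$is_inhibitory)))
  cat(sprintf("trials: %d | seizures: %d | wavefront annotations: %d\n",
              nrow(object@trials), nrow(object@seizures),
              nrow(object@frontLines)))
  if (length(object@groundTruth))
    cat("simulated experiment with ground truth\n")
})
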