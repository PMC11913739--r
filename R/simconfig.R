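#' Default photostimulation gain versus signed wavefront distance
#'
#' Piecewise-constant gain multiplier applied to the interictal evoked
#' amplitude of a photostimulation target during ictal trials, as a function
#' of the target's signed distance to the seizure wavefront (positive on the
#' penumbral, not-yet-recruited side). The default encodes the qualitative
#' excitability profile the analysis is meant to recover: strong suppression
#' inside the core (d < 0), suppression just ahead of the wavefront
#' (0 <= d < 100 um), unchanged excitability at 100-200 um, and facilitation
#' beyond 200 um. The step magnitudes are free simulator parameters, not
#' measured quantities.
#'
#' @param d numeric vector of signed distances to the wavefront (um).
#' @return numeric vector of non-negative gain multipliers.
#' @examples
#' defaultFrontGain(c(-50, 50, 150, 250))
#' @export
defaultFrontGain <- function(d) {
  out <- rep(1.0, length(d))
  out[d < 0] <- 0.1
  out[d >= 0 & d < 100] <- 0.3
  out[d > 200] <- 1.5
  out
}

#' Default target-to-non-target coupling kernel
#'
#' Signed coupling weight between a photostimulated target and a non-targeted
#' neuron at pairwise distance \code{d}: excitatory (+w) within 25 um,
#' inhibitory (-w) from 25 to 200 um, zero beyond. A non-target's evoked
#' response on a trial is the sum over targets of this weight times the
#' target's evoked amplitude.
#'
#' @param d numeric vector of pairwise distances (um).
#' @param w coupling magnitude (dimensionless multiplier on the target's
#'   evoked amplitude).
#' @return numeric vector of signed weights.
#' @examples
#' defaultCouplingKernel(c(10, 100, 300), w = 0.1)
#' @export
defaultCouplingKernel <- function(d, w = 0.1) {
  out <- numeric(length(d))
  out[d <= 25] <- w
  out[d > 25 & d <= 200] <- -w
  out
}

#' Build a synthetic-experiment configuration
#'
#' Constructs a \code{\linkS4class{SimConfig}} with defaults that emulate the
#' structure of an awake head-fixed all-optical experiment in the focal 4-AP
#' seizure model: a ~1 mm field of view imaged at 15 Hz, GCaMP6s-like
#' transient kinetics, a linear seizure wavefront sweeping the field at
#' constant speed, a regular photostimulation trial grid with 0.25 s
#' protocols, distance-dependent ictal gain, short-range excitatory /
#' mid-range inhibitory coupling onto non-targets, and post-ictal suppression.
#'
#' @param fov field of view (width, height) in um.
#' @param n_neurons number of neurons.
#' @param frac_targets,frac_inhibitory class fractions; targets are drawn from
#'   the non-inhibitory pool.
#' @param frame_rate imaging rate (Hz).
#' @param duration recording length (s).
#' @param injection_time convulsant injection time (s); earlier trials are
#'   baseline.
#' @param transient_rate,transient_amp,transient_tau spontaneous transient
#'   rate (events/s), amplitude (dF/F) and decay constant (s).
#' @param noise_sd per-frame Gaussian noise SD (dF/F).
#' @param seizure_times scheduled seizure onsets (s), all after
#'   \code{injection_time}.
#' @param seizure_duration seizure length (s).
#' @param wavefront_speed propagation speed (um/s).
#' @param wavefront_direction propagation direction (normalized internally).
#' @param seizure_plateau ictal plateau amplitude (dF/F).
#' @param recruit_rise_tau sigmoidal recruitment rise time constant (s).
#' @param postictal_suppression,postictal_window multiplicative suppression
#'   factor in (0, 1] and its duration (s) after seizure offset.
#' @param stim_start,stim_period,stim_duration photostimulation grid (s).
#' @param stim_gain_interictal evoked target amplitude outside seizures
#'   (dF/F).
#' @param gain_vs_front_distance gain function of signed wavefront distance;
#'   see \code{\link{defaultFrontGain}}.
#' @param coupling_weight,coupling_kernel coupling magnitude and kernel; see
#'   \code{\link{defaultCouplingKernel}}.
#' @param shared_fluctuation_sd SD of the shared per-trial fluctuation
#'   (multiplies evoked amplitudes and the global network response).
#' @param stim_global_amp amplitude (dF/F) of the additive network response
#'   of every neuron to ensemble photostimulation.
#' @param trigger_prob,trigger_jitter_sd probability that a post-injection
#'   trial triggers a seizure and the onset jitter SD (s).
#' @param baseline_f0 per-neuron baseline fluorescence range (a.u.).
#' @param roi_radius soma radius (um) for rendered masks.
#' @param stim_modality "twophoton" or "widefield".
#' @param seed integer seed; identical seeds give bit-identical experiments.
#' @return A validated \code{SimConfig}.
#' @examples
#' cfg <- simConfig(n_neurons = 30, duration = 130, injection_time = 30,
#'                  seizure_times = c(60, 100), seizure_duration = 15,
#'                  seed = 7)
#' @export
simConfig <- function(fov = c(1000, 1000),
                      n_neurons = 200,
                      frac_targets = 0.2,
                      frac_inhibitory = 0.1,
                      frame_rate = 15,
                      duration = 600,
                      injection_time = 200,
                      transient_rate = 0.1,
                      transient_amp = 1,
                      transient_tau = 1,
                      noise_sd = 0.1,
                      seizure_times = numeric(0),
                      seizure_duration = 20,
                      wavefront_speed = 300,
                      wavefront_direction = c(1, 0),
                      seizure_plateau = 4,
                      recruit_rise_tau = 0.1,
                      postictal_suppression = 0.5,
                      postictal_window = 30,
                      stim_start = 5,
                      stim_period = 5,
                      stim_duration = 0.25,
                      stim_gain_interictal = 0.2,
                      gain_vs_front_distance = defaultFrontGain,
                      coupling_weight = 0.1,
                      coupling_kernel = defaultCouplingKernel,
                      shared_fluctuation_sd = 0.2,
                      stim_global_amp = 0.05,
                      trigger_prob = 0,
                      trigger_jitter_sd = 0.2,
                      baseline_f0 = c(80, 120),
                      roi_radius = 6,
                      stim_modality = c("twophoton", "widefield"),
                      seed = 1L) {
  stim_modality <- match.arg(stim_modality)
  new("SimConfig",
      fov = as.numeric(fov), n_neurons = as.integer(n_neurons),
      frac_targets = frac_targets, frac_inhibitory = frac_inhibitory,
      frame_rate = frame_rate, duration = duration,
      injection_time = injection_time,
      transient_rate = transient_rate, transient_amp = transient_amp,
      transient_tau = transient_tau, noise_sd = noise_sd,
      seizure_times = sort(as.numeric(seizure_times)),
      seizure_duration = seizure_duration,
      wavefront_speed = wavefront_speed,
      wavefront_direction = .unit(as.numeric(wavefront_direction)),
      seizure_plateau = seizure_plateau, recruit_rise_tau = recruit_rise_tau,
      postictal_suppression = postictal_suppression,
      postictal_window = postictal_window,
      stim_start = stim_start, stim_period = stim_period,
      stim_duration = stim_duration,
      stim_gain_interictal = stim_gain_interictal,
      gain_vs_front_distance = gain_vs_front_distance,
      coupling_weight = coupling_weight, coupling_kernel = coupling_kernel,
      shared_fluctuation_sd = shared_fluctuation_sd,
      stim_global_amp = stim_global_amp,
      trigger_prob = trigger_prob, trigger_jitter_sd = trigger_jitter_sd,
      baseline_f0 = as.numeric(baseline_f0), roi_radius = roi_radius,
      stim_modality = stim_modality, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d neurons in %.0f x %.0f um, %.3g Hz, %.4g s\n",
              object@n_neurons, object@fov[1], object@fov[2],
              object@frame_rate, object@duration))
  cat(sprintf("  seizures: %d scheduled (%.3g s), front %.3g um/s along (%.2f, %.2f)\n",
              length(object@seizure_times), object@seizure_duration,
              object@wavefront_speed, object@wavefront_direction[1],
              object@wavefront_direction[2]))
  cat(sprintf("  stim: every %.3g s, %.3g s protocol, gain %.3g dF/F (%s)\n",
              object@stim_period, object@stim_duration,
              object@stim_gain_interictal, object@stim_modality))
  cat(sprintf("  seed: %d\n", object@seed))
})
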