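## Shared tiny configurations for fast tests. Kept deliberately small; the
## acceptance suite uses the full benchmark configs.

quickConfig <- function(...) {
  args <- list(...)
  defaults <- list(n_neurons = 20, fov = c(400, 400), duration = 60,
                   injection_time = 20, frame_rate = 15, seed = 1L)
  do.call(simConfig, utils::modifyList(defaults, args))
}

## a small experiment with one seizure crossing the field
quickSeizureExperiment <- function(seed = 1L, ...) {
  simulateExperiment(quickConfig(duration = 80, seizure_times = 40,
                                 seizure_duration = 10, seed = seed, ...))
}
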