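# Shared fixtures: the simulated On-midget scenario and spike matching.

midget_stimulus <- function(duration = 2.5, phase_zero = 0.5) {
  stimulus_spec(background_intensity = 600, contrast_percent = 80,
                frequency = 1, spot_diameter = 200,
                duration = duration, phase_zero = phase_zero)
}

# one current-clamp trial of the default On-midget scenario
sim_cc_trial <- function(condition = "control", seed = 1, fs = 10000,
                         stim_spec = midget_stimulus(),
                         cell = cell_model(),
                         drive_spec = synaptic_drive_spec()) {
  stim <- make_stimulus(stim_spec, fs)
  dr <- build_synaptic_drive(drive_spec, stim, condition, seed = seed)
  simulate_current_clamp(cell, dr)
}

as_train <- function(times, duration) {
  structure(list(spike_times = times, sweep_duration = duration,
                 threshold_sd = NA, sampling_rate = NA, cell_id = "fixture"),
            class = "spike_train")
}

# hits: truth spikes with a detection within tol; extras: detections with
# no truth spike within tol
match_spikes <- function(detected, truth, tol = 0.001) {
  hits <- if (length(truth)) {
    sum(vapply(truth, function(t0) {
      length(detected) && min(abs(detected - t0)) <= tol
    }, logical(1)))
  } else 0L
  extras <- if (length(detected)) {
    sum(vapply(detected, function(t0) {
      !length(truth) || min(abs(truth - t0)) > tol
    }, logical(1)))
  } else 0L
  list(hits = hits, extras = extras)
}
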