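# Shared fixtures: everything is generated in code at test time.

std_stim <- function(total = 120) stim_params(2, total_duration = total)

preset_params <- function(label) phenotype_preset(label)$params

# Phase series built directly from a phi vector (bypasses event
# interpolation; for closed-form oracle inputs).
make_phase_series <- function(phi, fs = 100, i0 = 0L) {
  structure(list(t = (i0:(i0 + length(phi) - 1L)) / fs, phi = phi,
                 fs = fs, i0 = as.integer(i0), events = NULL),
            class = "phase_series")
}

# Relative-phase series built directly from a wrapped dphi vector.
make_rp <- function(dphi, fs = 100) {
  entrainkit:::new_relative_phase((0:(length(dphi) - 1L)) / fs, dphi, fs)
}

# Coherence series built directly from a gamma vector.
make_cs <- function(gamma, fs = 100, t0 = 0, window_w = 3) {
  structure(list(t = t0 + (0:(length(gamma) - 1L)) / fs, gamma = gamma,
                 window_w = window_w, fs = fs),
            class = "coherence_series")
}

# Periodic event series helper.
periodic_events <- function(period, n, t0 = 0, label = "output") {
  event_series(t0 + period * (0:(n - 1)), label = label)
}

# One forced trial under a preset with the standard 2-min matched stimulus.
preset_trial <- function(label, seed, total = 120) {
  simulate_forced_trial(preset_params(label), std_stim(total), seed = seed)
}

phases_of <- function(trial, fs = 100) {
  list(inp = instantaneous_phase(trial$input_events, fs),
       out = instantaneous_phase(trial$output_events, fs))
}
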