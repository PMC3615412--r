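#' Oscillator parameters for the synthetic respiratory rhythm
#'
#' Parameter bundle for the noisy limit-cycle oscillator used to emulate
#' inspiratory motor output. The unforced cycle period is drawn per cycle as
#' `T = (1/omega0) * max(0.2, 1 + cv_period * xi)` with `xi` standard normal
#' (the 0.2 floor keeps periods physical); with per-cycle probability
#' `apnea_rate / (60 * omega0)` the cycle is prolonged by `apnea_scale`, which
#' models an apnea. `cv_period` is therefore the coefficient of variation of
#' the *normocyclic* (non-apneic) period.
#'
#' @param omega0 intrinsic burst rate, cycles/s (> 0).
#' @param cv_period cycle-to-cycle coefficient of variation of the unforced
#'   period (>= 0, dimensionless).
#' @param apnea_rate expected apneas per minute (>= 0).
#' @param apnea_scale multiplicative prolongation of apneic cycles; must be
#'   > 1.5 so that injected apneas are detectable by the 1.5 x mean-period
#'   rule (see [apnea_index()]). Default 2.5.
#' @param ti_fraction inspiratory fraction of the cycle, in (0, 1).
#' @param coupling_k phase-advance gain per stimulus, radians (>= 0).
#' @param prc_shape phase-response curve family. `"hbr"` (default) mimics the
#'   Hering-Breuer reflex: a stimulus in late inspiration advances the phase
#'   toward the inspiratory off-switch (shortening Ti), while a stimulus in
#'   expiration prolongs expiration (phase delay, zero at both expiratory
#'   ends); the stable 1:1 lock then sits at the I->E transition, which
#'   reproduces both entrainment and the Ti reduction under stimulation.
#'   `"expiratory_sine"` applies `Z(phi) = sin(phi)` during expiration plus
#'   the same off-switch advance; `"pure_sine"` is `Z(phi) = sin(phi)`
#'   everywhere with no off-switch.
#' @param seed default RNG seed carried with the parameters (integer or NULL).
#' @return an object of class `osc_params`.
#' @seealso [phenotype_preset()], [simulate_unforced_epoch()],
#'   [simulate_forced_trial()]
#' @export
osc_params <- function(omega0, cv_period = 0, apnea_rate = 0,
                       apnea_scale = 2.5, ti_fraction = 0.4,
                       coupling_k = 0,
                       prc_shape = c("hbr", "expiratory_sine", "pure_sine"),
                       seed = NULL) {
  prc_shape <- match.arg(prc_shape)
  if (!is.numeric(omega0) || omega0 <= 0) stop_parameter("omega0 must be > 0")
  if (cv_period < 0) stop_parameter("cv_period must be >= 0")
  if (apnea_rate < 0) stop_parameter("apnea_rate must be >= 0")
  if (apnea_scale <= 1.5) {
    stop_parameter("apnea_scale must be > 1.5 (apneas must be detectable)")
  }
  if (ti_fraction <= 0 || ti_fraction >= 1) {
    stop_parameter("ti_fraction must be in (0, 1)")
  }
  if (coupling_k < 0) stop_parameter("coupling_k must be >= 0")
  structure(list(omega0 = omega0, cv_period = cv_period,
                 apnea_rate = apnea_rate, apnea_scale = apnea_scale,
                 ti_fraction = ti_fraction, coupling_k = coupling_k,
                 prc_shape = prc_shape, seed = seed),
            class = "osc_params")
}

#' Stimulus-train parameters
#'
#' Describes a free-running periodic train of stimulus bursts. Only train
#' onsets and the train envelope width enter the analysis; the individual
#' high-frequency pulses inside a train (75 Hz, 0.5 ms in the experiments this
#' emulates) are far below the cycle-scale resolution of every statistic and
#' are represented by a single 100 ms burst envelope.
#'
#' @param inter_burst_freq trains per second (> 0); matched to the intrinsic
#'   oscillation frequency in the standard protocol.
#' @param train_duration train envelope width, s; must lie in
#'   (0, 1/inter_burst_freq). Default 0.1.
#' @param total_duration trial length, s. Default 120 (a 2-min trial).
#' @param start_phase_offset delay of the first train from trial start, s.
#' @return an object of class `stim_params`.
#' @export
stim_params <- function(inter_burst_freq, train_duration = 0.1,
                        total_duration = 120, start_phase_offset = 0) {
  if (!is.numeric(inter_burst_freq) || inter_burst_freq <= 0) {
    stop_parameter("inter_burst_freq must be > 0")
  }
  if (train_duration <= 0 || train_duration >= 1 / inter_burst_freq) {
    stop_parameter("train_duration must be in (0, 1/inter_burst_freq)")
  }
  if (total_duration <= 0) stop_parameter("total_duration must be > 0")
  if (start_phase_offset < 0 || start_phase_offset >= total_duration) {
    stop_parameter("start_phase_offset must be in [0, total_duration)")
  }
  structure(list(inter_burst_freq = inter_burst_freq,
                 train_duration = train_duration,
                 total_duration = total_duration,
                 start_phase_offset = start_phase_offset),
            class = "stim_params")
}

#' Phenotype presets
#'
#' Canonical simulator parameter bundles emulating the three trial groups the
#' analysis is designed to separate: a wild-type-like oscillator (low period
#' variability, no apneas, strong 1:1 coupling), an intermediate phenotype
#' (raised variability, weak but real coupling), and a severe phenotype (high
#' variability, ~3.7 apneas/min, no coupling at all).
#'
#' @param label one of `"wildtype"`, `"intermediate"`, `"severe"`.
#' @param seed optional RNG seed stored in the preset's parameters.
#' @return a list with fields `label` and `params` (an [osc_params()]),
#'   of class `phenotype_preset`.
#' @examples
#' phenotype_preset("severe")$params$cv_period  # 0.23
#' @export
phenotype_preset <- function(label = c("wildtype", "intermediate", "severe"),
                             seed = NULL) {
  label <- match.arg(label)
  params <- switch(label,
    wildtype = osc_params(omega0 = 2, cv_period = 0.09, apnea_rate = 0,
                          ti_fraction = 0.40, coupling_k = 1.5, seed = seed),
    intermediate = osc_params(omega0 = 2, cv_period = 0.16, apnea_rate = 1.5,
                              ti_fraction = 0.35, coupling_k = 0.4,
                              seed = seed),
    severe = osc_params(omega0 = 2, cv_period = 0.23, apnea_rate = 3.7,
                        ti_fraction = 0.35, coupling_k = 0, seed = seed)
  )
  structure(list(label = label, params = params), class = "phenotype_preset")
}

#' Generate a periodic stimulus train
#'
#' Train onsets are the arithmetic sequence
#' `t_j = start_phase_offset + j / inter_burst_freq`, `j = 0, 1, ...`, keeping
#' all onsets strictly less than `total_duration` (an onset falling exactly on
#' the trial end is excluded).
#'
#' @param sp a [stim_params()] bundle.
#' @return an `event_series` labelled `"input"`, with the train duration
#'   attached as attribute `train_duration`.
#' @examples
#' ev <- generate_stimulus_train(stim_params(2, total_duration = 10))
#' n_events(ev)  # 20
#' @export
generate_stimulus_train <- function(sp) {
  stopifnot(inherits(sp, "stim_params"))
  j_max <- ceiling((sp$total_duration - sp$start_phase_offset) *
                     sp$inter_burst_freq) + 1
  times <- sp$start_phase_offset + (0:j_max) / sp$inter_burst_freq
  times <- times[times < sp$total_duration]
  ev <- event_series(times, label = "input")
  attr(ev, "train_duration") <- sp$train_duration
  ev
}

# Draw n unforced cycle periods (seconds) under params p.
draw_periods <- function(p, n) {
  periods <- (1 / p$omega0) * pmax(0.2, 1 + p$cv_period * rnorm(n))
  if (p$apnea_rate > 0) {
    apneic <- runif(n) < p$apnea_rate / (60 * p$omega0)
    periods[apneic] <- periods[apneic] * p$apnea_scale
  }
  periods
}

new_simulated_trial <- function(input_events, output_events, output_offsets,
                                params, stim = NULL) {
  structure(list(input_events = input_events,
                 output_events = output_events,
                 output_offsets = output_offsets,
                 params = params, stim = stim),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf("<simulated_trial: %d output bursts%s>\n",
              n_events(x$output_events),
              if (!is.null(x$input_events)) {
                sprintf(", %d input trains", n_events(x$input_events))
              } else ""))
  invisible(x)
}

#' Simulate an unforced (baseline) epoch
#'
#' Cycle periods are i.i.d. draws from the oscillator's period model (see
#' [osc_params()]); onsets are their cumulative sums starting at t = 0, and
#' each burst offset falls at `onset + ti_fraction * period`. A final burst
#' whose offset would fall beyond `duration` is dropped so that offsets always
#' interleave one-per-onset.
#'
#' @param p an [osc_params()] bundle.
#' @param duration epoch length, s (> 0).
#' @param seed RNG seed; defaults to `p$seed`. The same seed gives a
#'   bit-identical trial.
#' @return a `simulated_trial` with `input_events = NULL`.
#' @examples
#' tr <- simulate_unforced_epoch(osc_params(2), duration = 10)
#' tr$output_events$times  # exactly periodic at 0.5 s in the zero-noise limit
#' @export
simulate_unforced_epoch <- function(p, duration, seed = p$seed) {
  stopifnot(inherits(p, "osc_params"))
  if (duration <= 0) stop_parameter("duration must be > 0")
  with_seed(seed, {
    n <- ceiling(duration * p$omega0 * 1.5) + 10
    periods <- draw_periods(p, n)
    while (sum(periods) < duration) {
      periods <- c(periods, draw_periods(p, n))
    }
    onsets <- c(0, cumsum(periods))
    k <- sum(onsets < duration)
    onsets <- onsets[seq_len(k)]
    offsets <- onsets + p$ti_fraction * periods[seq_len(k)]
    if (k > 0 && offsets[k] >= duration) {
      onsets <- onsets[-k]
      offsets <- offsets[-k]
    }
    new_simulated_trial(NULL, event_series(onsets, "output"),
                        offsets, p)
  })
}

# Phase-response curve: instantaneous phase shift applied at a stimulus.
# phi_ti is the inspiratory-expiratory boundary phase (2*pi*ti_fraction).
# Returns the post-kick phase together with whether the kick crossed phi_ti
# (terminating inspiration).
apply_prc_kick <- function(phi, k, phi_ti, prc_shape) {
  crossed_ti <- FALSE
  if (k > 0) {
    if (prc_shape == "pure_sine") {
      phi_new <- phi + k * sin(phi)
      if (phi >= phi_ti) phi_new <- max(phi_new, phi_ti)
      if (phi < phi_ti && phi_new >= phi_ti) crossed_ti <- TRUE
      phi <- phi_new
    } else if (phi >= phi_ti) {
      # expiratory phase shift; clamped so a delay cannot re-enter
      # inspiration (the offset for this cycle has already occurred)
      z <- if (prc_shape == "hbr") {
        # expiratory prolongation (delay), zero at both expiratory ends
        -sin(pi * (phi - phi_ti) / (2 * pi - phi_ti))
      } else {
        sin(phi)
      }
      phi <- max(phi + k * z, phi_ti)
    } else if (phi >= 0.5 * phi_ti) {
      # late inspiration: off-switch advance toward the Ti boundary
      phi <- phi + min(k, 1) * (phi_ti - phi)
      if (phi >= phi_ti * (1 - 1e-12)) {
        phi <- phi_ti
        crossed_ti <- TRUE
      }
    }
    # early inspiration: refractory, no effect
  }
  phi <- min(phi, 2 * pi - 1e-9)
  list(phi = phi, crossed_ti = crossed_ti)
}

#' Simulate a 2-min style forced stimulation trial
#'
#' Pulse-coupled noisy phase oscillator. Within each cycle the phase advances
#' linearly at rate `2*pi / T` with the cycle period `T` drawn from the same
#' model as [simulate_unforced_epoch()] (so `coupling_k = 0` reduces exactly
#' to the unforced statistics). Each stimulus-train onset applies an
#' instantaneous phase shift `coupling_k * Z(phi)` given by the selected
#' phase-response curve; a burst onset is emitted at every 2*pi crossing and a
#' burst offset when the phase crosses `2*pi*ti_fraction` (by flow or by an
#' off-switch kick, which is how stimulation shortens Ti). Stimulation is
#' free-running: trains are not triggered by the output, and the initial
#' oscillator phase is uniform random.
#'
#' @param p an [osc_params()] bundle.
#' @param sp a [stim_params()] bundle.
#' @param seed RNG seed; defaults to `p$seed`.
#' @return a `simulated_trial` with input and output event series, output
#'   offsets, and the generating parameters.
#' @export
simulate_forced_trial <- function(p, sp, seed = p$seed) {
  stopifnot(inherits(p, "osc_params"), inherits(sp, "stim_params"))
  with_seed(seed, {
    stim <- generate_stimulus_train(sp)
    total <- sp$total_duration
    phi_ti <- 2 * pi * p$ti_fraction
    k <- p$coupling_k

    phi <- runif(1, 0, 2 * pi)
    rate <- 2 * pi / draw_periods(p, 1)
    onsets <- numeric(0)
    offsets <- numeric(0)
    have_onset <- FALSE      # current cycle began with a recorded onset
    offset_done <- phi >= phi_ti
    t_cur <- 0

    bounds <- c(stim$times[stim$times > 0], total)
    for (s in bounds) {
      # advance the flow to time s, emitting Ti crossings and wraps
      repeat {
        t_off <- if (!offset_done) t_cur + (phi_ti - phi) / rate else Inf
        t_wrap <- t_cur + (2 * pi - phi) / rate
        nxt <- min(t_off, t_wrap)
        if (nxt > s) {
          phi <- phi + rate * (s - t_cur)
          t_cur <- s
          break
        }
        if (t_off <= t_wrap) {
          if (have_onset) offsets <- c(offsets, t_off)
          offset_done <- TRUE
          phi <- phi_ti
          t_cur <- t_off
        } else {
          onsets <- c(onsets, t_wrap)
          have_onset <- TRUE
          phi <- 0
          rate <- 2 * pi / draw_periods(p, 1)
          offset_done <- FALSE
          t_cur <- t_wrap
        }
      }
      if (s < total) {
        kick <- apply_prc_kick(phi, k, phi_ti, p$prc_shape)
        if (kick$crossed_ti && !offset_done) {
          if (have_onset) offsets <- c(offsets, s)
          offset_done <- TRUE
        }
        phi <- kick$phi
      }
    }

    # keep only complete onset/offset pairs inside [0, total)
    keep <- offsets < total
    offsets <- offsets[keep]
    if (length(onsets) > length(offsets)) {
      onsets <- onsets[seq_along(offsets)]
    }
    new_simulated_trial(stim, event_series(onsets, "output"), offsets, p, sp)
  })
}

#' Render a synthetic integrated-burst trace
#'
#' Builds a continuous trace from a trial's output bursts: within each
#' onset-offset pair the envelope ramps from 0.75 up to 1 (mimicking the
#' augmenting profile of integrated inspiratory activity), drops at the
#' offset, and decays as a sub-threshold exponential tail (peak 0.45, tau
#' 30 ms); additive Gaussian noise is optional. In the noiseless case the
#' trace exceeds 0.5 exactly on each [onset, offset) interval, so
#' [detect_bursts()] at threshold 0.5 recovers the generating events.
#'
#' @param trial a `simulated_trial` (its output events/offsets are rendered).
#' @param fs sampling rate, Hz.
#' @param noise_sd standard deviation of additive Gaussian noise, a.u.
#' @param t_range time range `c(t0, t1)` to render; defaults to the trial's
#'   stimulation span or `[0, last offset + 0.5]`.
#' @param seed optional RNG seed for the noise.
#' @return a `continuous_trace`.
#' @export
render_trace <- function(trial, fs = 1000, noise_sd = 0, t_range = NULL,
                         seed = NULL) {
  if (fs <= 0) stop_parameter("fs must be > 0")
  onsets <- trial$output_events$times
  offsets <- trial$output_offsets
  if (is.null(t_range)) {
    t1 <- if (!is.null(trial$stim)) {
      trial$stim$total_duration
    } else if (length(offsets)) {
      max(offsets) + 0.5
    } else 1
    t_range <- c(0, t1)
  }
  with_seed(seed, {
    t <- seq(t_range[1], t_range[2], by = 1 / fs)
    v <- numeric(length(t))
    for (i in seq_along(onsets)) {
      on <- onsets[i]; off <- offsets[i]
      idx <- which(t >= on & t < off)
      if (length(idx)) {
        v[idx] <- pmax(v[idx], 0.75 + 0.25 * (t[idx] - on) / (off - on))
      }
      tail_idx <- which(t >= off & t < off + 0.2)
      if (length(tail_idx)) {
        v[tail_idx] <- pmax(v[tail_idx],
                            0.45 * exp(-(t[tail_idx] - off) / 0.03))
      }
    }
    if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
    continuous_trace(t, v)
  })
}
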