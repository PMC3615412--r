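two_pi <- 2 * pi

# Uniform sample grid covering [t1, tK] with samples at integer multiples of
# 1/fs. Returning the integer index range makes intersecting the domains of
# two series exact.
phase_grid <- function(t1, tK, fs) {
  i0 <- ceiling(t1 * fs - 1e-9)
  i1 <- floor(tK * fs + 1e-9)
  list(i0 = i0, i1 = i1, t = (i0:i1) / fs)
}

# Piecewise-linear instantaneous phase of an event train at times tt
# (tt must lie within [first event, last event]).
phase_at <- function(times, tt) {
  K <- length(times)
  idx <- findInterval(tt, times)
  idx <- pmin(pmax(idx, 1L), K - 1L)
  phi <- two_pi * (tt - times[idx]) / (times[idx + 1L] - times[idx])
  phi[phi >= two_pi] <- 0
  phi[phi < 0] <- 0
  phi
}

#' Instantaneous phase from event onsets
#'
#' Assigns to every time between consecutive events a phase growing linearly
#' from 0 to 2*pi: for `t_k <= t < t_{k+1}`,
#' `phi(t) = 2*pi * (t - t_k) / (t_{k+1} - t_k)`. The phase wraps exactly at
#' event times (`phi(t_k) = 0`) and is sampled on the uniform grid of rate
#' `fs_phase` restricted to `[t_1, t_K]`. Grid samples sit at integer
#' multiples of `1/fs_phase`, so two series sampled at the same rate share
#' grid points on their common domain.
#'
#' @param ev an [event_series()] with at least 2 events.
#' @param fs_phase sampling rate of the phase series, Hz. Default 100,
#'   far above typical burst rates so that histogram and window statistics
#'   are insensitive to it.
#' @return an object of class `phase_series`: fields `t`, `phi` (radians in
#'   `[0, 2*pi)`), `fs`, and the source events.
#' @examples
#' ps <- instantaneous_phase(event_series(c(0, 1, 2)), fs_phase = 100)
#' ps$phi[ps$t == 0.5]  # pi
#' @export
instantaneous_phase <- function(ev, fs_phase = 100) {
  stopifnot(inherits(ev, "event_series"))
  if (n_events(ev) < 2) stop_insufficient("need at least 2 events")
  if (fs_phase <= 0) stop_parameter("fs_phase must be > 0")
  g <- phase_grid(ev$times[1], ev$times[n_events(ev)], fs_phase)
  structure(list(t = g$t, phi = phase_at(ev$times, g$t), fs = fs_phase,
                 i0 = g$i0, events = ev),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series: %d samples @ %g Hz over [%.3f, %.3f] s>\n",
              length(x$t), x$fs, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

# Overlap of two phase series sampled on the same integer grid.
common_samples <- function(a, b) {
  if (abs(a$fs - b$fs) > 1e-9) {
    stop_parameter("phase series must share the same sampling rate")
  }
  i0 <- max(a$i0, b$i0)
  i1 <- min(a$i0 + length(a$t) - 1L, b$i0 + length(b$t) - 1L)
  if (i1 < i0) stop_insufficient("phase series domains do not overlap")
  list(t = (i0:i1) / a$fs,
       a = a$phi[(i0 - a$i0 + 1L):(i1 - a$i0 + 1L)],
       b = b$phi[(i0 - b$i0 + 1L):(i1 - b$i0 + 1L)])
}

# Construct a relative-phase series directly from a wrapped sample vector
# (used internally and by tests that need hand-built inputs).
new_relative_phase <- function(t, dphi, fs) {
  d <- diff(dphi)
  d <- d - two_pi * round(d / two_pi)   # minimal-magnitude increments
  structure(list(t = t, dphi = dphi %% two_pi,
                 dphi_unwrapped = dphi[1] + c(0, cumsum(d)), fs = fs),
            class = "relative_phase_series")
}

#' Relative phase of output vs input
#'
#' Computes `phi_output - phi_input` on the intersection of the two domains,
#' both wrapped to `[0, 2*pi)` and unwrapped by accumulating
#' minimal-magnitude increments between successive samples. Epochs where the
#' unwrapped series has near-zero slope are entrained; full 2*pi excursions
#' are phase slips.
#'
#' @param out_ps,in_ps [instantaneous_phase()] series sampled at the same
#'   rate.
#' @return an object of class `relative_phase_series`: fields `t`, `dphi`
#'   (wrapped), `dphi_unwrapped`, `fs`.
#' @export
relative_phase <- function(out_ps, in_ps) {
  stopifnot(inherits(out_ps, "phase_series"), inherits(in_ps, "phase_series"))
  cs <- common_samples(out_ps, in_ps)
  new_relative_phase(cs$t, cs$a - cs$b, out_ps$fs)
}

#' @export
print.relative_phase_series <- function(x, ...) {
  cat(sprintf("<relative_phase_series: %d samples over [%.3f, %.3f] s>\n",
              length(x$t), x$t[1], x$t[length(x$t)]))
  invisible(x)
}

wrap_bins <- function(x, n_bins) {
  b <- floor((x %% two_pi) / two_pi * n_bins)
  b[b >= n_bins] <- n_bins - 1L
  b[b < 0] <- 0L
  as.integer(b) + 1L
}

#' Relative-phase histogram
#'
#' Probability histogram of the wrapped relative phase over `[0, 2*pi)`
#' (default 21 bins). The maximum bin probability is the standard coupling
#' index: 1 for perfect locking at one phase, ~ 1/n_bins for a drifting,
#' uniform relative phase.
#'
#' @param rp a [relative_phase()] series, or a raw numeric vector of angles
#'   (radians).
#' @param n_bins number of bins; default 21.
#' @return a list of class `relative_phase_histogram`: `breaks`, `counts`,
#'   `prob`, `max_prob`, `mode_bin`.
#' @export
relative_phase_histogram <- function(rp, n_bins = 21) {
  x <- if (inherits(rp, "relative_phase_series")) rp$dphi else as.numeric(rp)
  if (!length(x)) stop_insufficient("need at least 1 sample")
  counts <- tabulate(wrap_bins(x, n_bins), nbins = n_bins)
  prob <- counts / sum(counts)
  structure(list(breaks = two_pi * (0:n_bins) / n_bins, counts = counts,
                 prob = prob, max_prob = max(prob),
                 mode_bin = which.max(prob)),
            class = "relative_phase_histogram")
}

#' Rayleigh test for circular uniformity
#'
#' Tests the null hypothesis that angles are uniform on the circle using the
#' mean resultant length `r_bar = |mean(exp(i*theta))|` and the statistic
#' `Z = n * r_bar^2`, with the standard small-sample series approximation for
#' the p value (clipped to `[0, 1]`).
#'
#' @param angles numeric vector of angles, radians; `n >= 2`.
#' @return a list of class `rayleigh_test`: `r_bar`, `Z`, `p`, `n`.
#' @export
rayleigh_test <- function(angles) {
  angles <- as.numeric(angles)
  n <- length(angles)
  if (n < 2) stop_insufficient("need at least 2 angles")
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  r_bar <- sqrt(C^2 + S^2)
  Z <- n * r_bar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  structure(list(r_bar = r_bar, Z = Z, p = min(max(p, 0), 1), n = n),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test: r_bar = %.4f, Z = %.3f, p = %.3g (n = %d)\n",
              x$r_bar, x$Z, x$p, x$n))
  invisible(x)
}

#' Sliding-window phase coherence
#'
#' The windowed squared magnitude of the circular mean of the relative phase:
#' `gamma(t) = |mean over [t - w, t] of exp(i * dphi)|^2`, using a trailing
#' window of `window_w` seconds (default 3 s). Values near 1 indicate
#' phase-locking; near 0, drifting. The series is only defined where the
#' window is complete.
#'
#' @param rp a [relative_phase()] series.
#' @param window_w window length, s.
#' @return an object of class `coherence_series`: `t`, `gamma` in `[0, 1]`,
#'   `window_w`, `fs`.
#' @export
phase_coherence <- function(rp, window_w = 3) {
  stopifnot(inherits(rp, "relative_phase_series"))
  N <- as.integer(round(window_w * rp$fs)) + 1L
  M <- length(rp$t)
  if (N < 2) stop_parameter("window must contain at least 2 samples")
  if (N > M) stop_insufficient("window longer than the series domain")
  cc <- cumsum(cos(rp$dphi))
  ss <- cumsum(sin(rp$dphi))
  j <- N:M
  sum_c <- cc[j] - c(0, cc)[j - N + 1L]
  sum_s <- ss[j] - c(0, ss)[j - N + 1L]
  gamma <- (sum_c / N)^2 + (sum_s / N)^2
  structure(list(t = rp$t[j], gamma = pmin(gamma, 1), window_w = window_w,
                 fs = rp$fs),
            class = "coherence_series")
}

#' Entrainment bouts, latency, and phase slips
#'
#' Bouts are the maximal contiguous runs where the coherence exceeds
#' `threshold` (default 0.9). Each bout is reported as a half-open interval:
#' its end is one sample step past the last supra-threshold sample, so a
#' constructed square-wave coherence of duration d yields a bout of exactly d
#' seconds. Latency is the first bout start minus `stim_start`; when no bout
#' occurs it is `NA` (censored), not a number. Phase slips are counted from
#' the unwrapped relative phase as completed 2*pi excursions
#' (`slip_method = "excursions"`, increments of `round(delta / 2*pi)`), or as
#' bout interruptions (`slip_method = "interruptions"`).
#'
#' @param cs a [phase_coherence()] series.
#' @param rp the matching [relative_phase()] series (optional; needed for
#'   excursion-based slip counting).
#' @param stim_start stimulation start time, s.
#' @param threshold coherence cutoff; default 0.9.
#' @param slip_method slip definition (see above).
#' @return a list of class `entrainment_bouts`: `bouts` (data.frame with
#'   `start`, `end`, `duration`), `n_bouts`, `latency`,
#'   `mean_bout_duration`, `total_bout_duration`, `n_slips`, `threshold`.
#' @export
detect_bouts <- function(cs, rp = NULL, stim_start = 0, threshold = 0.9,
                         slip_method = c("excursions", "interruptions")) {
  stopifnot(inherits(cs, "coherence_series"))
  slip_method <- match.arg(slip_method)
  dt <- 1 / cs$fs
  above <- cs$gamma > threshold
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  sel <- which(r$values)
  bouts <- data.frame(start = cs$t[starts_idx[sel]],
                      end = cs$t[ends_idx[sel]] + dt)
  bouts$duration <- bouts$end - bouts$start
  latency <- if (nrow(bouts)) max(bouts$start[1] - stim_start, 0) else NA_real_
  n_slips <- NA_integer_
  if (slip_method == "interruptions") {
    n_slips <- max(0L, nrow(bouts) - 1L)
  } else if (!is.null(rp)) {
    u <- rp$dphi_unwrapped[rp$t >= stim_start]
    if (length(u) > 1) {
      kturn <- round((u - u[1]) / two_pi)
      n_slips <- sum(abs(diff(kturn)))
    }
  }
  structure(list(bouts = bouts, n_bouts = nrow(bouts), latency = latency,
                 mean_bout_duration = if (nrow(bouts)) mean(bouts$duration)
                                      else NA_real_,
                 total_bout_duration = sum(bouts$duration),
                 n_slips = n_slips, threshold = threshold),
            class = "entrainment_bouts")
}

#' @export
print.entrainment_bouts <- function(x, ...) {
  cat(sprintf(paste0("<entrainment_bouts: %d bout(s), latency %s s, ",
                     "mean duration %s s, %s slip(s)>\n"),
              x$n_bouts,
              if (is.na(x$latency)) "NA" else sprintf("%.2f", x$latency),
              if (is.na(x$mean_bout_duration)) "NA"
              else sprintf("%.2f", x$mean_bout_duration),
              if (is.na(x$n_slips)) "NA" else x$n_slips))
  invisible(x)
}

#' Synchronization index (phase-locking value)
#'
#' The modulus of the time average of `exp(i * (n*phi_output - m*phi_input))`
#' over the common domain of the two series: 1 for perfect n:m locking, ~ 0
#' for independent phases. With the default `n = m = 1` this is the mean
#' resultant vector of the relative phase; its square equals the unwindowed
#' phase coherence over the same epoch.
#'
#' @param out_ps,in_ps [instantaneous_phase()] series at the same rate.
#' @param n,m integer locking ratio; default 1:1.
#' @return a single numeric value in `[0, 1]`.
#' @export
synchronization_index <- function(out_ps, in_ps, n = 1, m = 1) {
  cs <- common_samples(out_ps, in_ps)
  sync_from_phases(cs$a, cs$b, n, m)
}

sync_from_phases <- function(phi_out, phi_in, n = 1, m = 1) {
  z <- exp(1i * (n * phi_out - m * phi_in))
  min(Mod(mean(z)), 1)
}
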