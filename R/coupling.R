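#' Square-wave representation of a stimulus train
#'
#' Represents an input event train as a 0/1 square wave: the signal is 1 on
#' `[event, event + pulse_width)` for each event and 0 elsewhere, sampled at
#' `fs` over `t_range`. This is the conventional input signal for the
#' cross-correlogram.
#'
#' @param ev an [event_series()].
#' @param pulse_width pulse (train envelope) width, s; defaults to the
#'   `train_duration` attribute attached by [generate_stimulus_train()].
#' @param fs sampling rate, Hz; default 1000.
#' @param t_range time range `c(t0, t1)`; defaults to `[0, last event +
#'   pulse_width]`.
#' @return a `continuous_trace` (additional class `square_wave`) with
#'   attribute `pulse_width`.
#' @export
square_wave <- function(ev, pulse_width = NULL, fs = 1000, t_range = NULL) {
  stopifnot(inherits(ev, "event_series"))
  pulse_width <- pulse_width %||% attr(ev, "train_duration")
  if (is.null(pulse_width) || pulse_width <= 0) {
    stop_parameter("pulse_width must be > 0")
  }
  if (is.null(t_range)) {
    t_range <- c(0, max(ev$times) + pulse_width)
  }
  t <- seq(t_range[1], t_range[2], by = 1 / fs)
  v <- numeric(length(t))
  for (e in ev$times) {
    idx <- which(t >= e & t < e + pulse_width)
    v[idx] <- 1
  }
  out <- continuous_trace(t, v)
  class(out) <- c("square_wave", class(out))
  attr(out, "pulse_width") <- pulse_width
  out
}

#' Normalized cross-correlogram of output vs input
#'
#' Both signals are min-max scaled to `[0, 1]` and DC-removed, then
#' cross-correlated under the correlation-coefficient convention (the
#' autocorrelation of either signal at lag 0 equals 1). The maximum over
#' `|lag| <= max_lag` is the coupling index; for an entrained pair the
#' correlogram shows periodic side-lobes decaying with lag. Positive lags
#' mean the output lags the input.
#'
#' @param out_sig output signal: a [continuous_trace()] (e.g. an integrated
#'   burst trace or rendered output square wave).
#' @param in_sw input square wave ([square_wave()]); must share the output's
#'   sampling rate and start time.
#' @param max_lag maximal lag magnitude, s; conventionally ~ 2 intrinsic
#'   periods. Defaults to a quarter of the signal duration, capped at 10 s.
#' @return a list of class `cross_correlogram`: `lag` (s), `cc`, `peak`,
#'   `peak_lag`.
#' @export
normalized_cross_correlogram <- function(out_sig, in_sw, max_lag = NULL) {
  stopifnot(inherits(out_sig, "continuous_trace"),
            inherits(in_sw, "continuous_trace"))
  if (abs(out_sig$fs - in_sw$fs) > 1e-6 * out_sig$fs) {
    stop_parameter("signals must share the same sampling rate")
  }
  if (abs(out_sig$time[1] - in_sw$time[1]) > 0.5 / out_sig$fs) {
    stop_parameter("signals must share the same start time")
  }
  n <- min(length(out_sig$value), length(in_sw$value))
  fs <- out_sig$fs
  max_lag <- max_lag %||% min((n - 1) / fs / 4, 10)
  if (max_lag <= 0 || max_lag >= (n - 1) / fs) {
    stop_parameter("max_lag must be in (0, signal duration)")
  }
  scale01 <- function(x) {
    r <- range(x)
    if (r[2] - r[1] <= 0) stop_parameter("degenerate input: constant signal")
    (x - r[1]) / (r[2] - r[1])
  }
  x <- scale01(out_sig$value[seq_len(n)])
  y <- scale01(in_sw$value[seq_len(n)])
  x <- x - mean(x)
  y <- y - mean(y)
  cc <- stats::ccf(x, y, lag.max = round(max_lag * fs), plot = FALSE,
                   demean = FALSE)
  lag_s <- drop(cc$lag) / fs
  val <- drop(cc$acf)
  i <- which.max(val)
  structure(list(lag = lag_s, cc = val, peak = val[i], peak_lag = lag_s[i]),
            class = "cross_correlogram")
}

#' @export
print.cross_correlogram <- function(x, ...) {
  cat(sprintf("<cross_correlogram: peak %.3f at lag %.3f s (%d lags)>\n",
              x$peak, x$peak_lag, length(x$lag)))
  invisible(x)
}

#' Joint histogram of instantaneous input and output phases
#'
#' Bivariate histogram of `(phi_output, phi_input)` over the uniform grid
#' samples of the common domain, `L x L` bins on `[0, 2*pi)^2` (default
#' L = 50, used consistently because mutual information depends on L).
#' Phase-locked pairs concentrate mass along a diagonal band; independent
#' drifting phases fill the square uniformly.
#'
#' @param out_ps,in_ps [instantaneous_phase()] series at the same rate.
#' @param L number of bins per axis; default 50.
#' @return a list of class `joint_phase_histogram`: `counts` (L x L matrix,
#'   rows = output bins), `P` (joint probabilities), `L`, `n`.
#' @export
joint_phase_histogram <- function(out_ps, in_ps, L = 50) {
  cs <- common_samples(out_ps, in_ps)
  joint_hist_from_phases(cs$a, cs$b, L)
}

joint_hist_from_phases <- function(phi_out, phi_in, L) {
  bx <- wrap_bins(phi_out, L)
  by <- wrap_bins(phi_in, L)
  counts <- matrix(tabulate((bx - 1L) * L + by, nbins = L * L),
                   nrow = L, ncol = L, byrow = TRUE)
  structure(list(counts = counts, P = counts / sum(counts), L = L,
                 n = length(bx)),
            class = "joint_phase_histogram")
}

#' Shannon entropy of a probability histogram (nats)
#'
#' `H = -sum(p * ln p)` with the convention `0 * ln 0 = 0`. Probabilities
#' must be non-negative and sum to 1 (within 1e-6).
#'
#' @param P numeric vector or matrix of probabilities.
#' @return entropy in nats.
#' @examples
#' entropy(rep(1/50, 50))  # ln 50 = 3.912
#' @export
entropy <- function(P) {
  p <- as.numeric(P)
  if (any(p < -1e-12)) stop_format("negative probabilities")
  if (abs(sum(p) - 1) > 1e-6) stop_format("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information of the instantaneous phases
#'
#' Computed from a joint phase histogram as
#' `I = H(phi_in) + H(phi_out) - H(phi_in, phi_out)` (nats), with the
#' marginal entropies taken from the joint histogram's marginals so that the
#' decomposition is exactly consistent. `formula = "as_printed"` instead
#' evaluates `H(in) + H(out) - H(in|out)` with the conditional entropy
#' `H(in|out) = H(in,out) - H(out)`, for comparison with sources that print
#' the conditional-entropy form.
#'
#' Note that binned MI carries a positive finite-sample bias of order
#' `(L-1)^2 / (2N)` nats; absolute values are comparable only at fixed `L`
#' and sample count, which is why significance is assessed against an
#' interval-shuffling surrogate distribution ([bootstrap_mi()]) that carries
#' the same bias.
#'
#' @param jh a [joint_phase_histogram()].
#' @param formula `"standard"` (default) or `"as_printed"`.
#' @return a list of class `mi_result`: `mi`, `h_in`, `h_out`, `h_joint`
#'   (nats), `L`, `formula`, `units`.
#' @export
mutual_information <- function(jh, formula = c("standard", "as_printed")) {
  stopifnot(inherits(jh, "joint_phase_histogram"))
  formula <- match.arg(formula)
  h_out <- entropy(rowSums(jh$P))
  h_in <- entropy(colSums(jh$P))
  h_joint <- entropy(jh$P)
  mi <- if (formula == "standard") {
    h_in + h_out - h_joint
  } else {
    h_in + h_out - (h_joint - h_out)
  }
  structure(list(mi = mi, h_in = h_in, h_out = h_out, h_joint = h_joint,
                 L = jh$L, formula = formula, units = "nats"),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("MI = %.4f nats (H_in %.3f, H_out %.3f, H_joint %.3f; L = %d)\n",
              x$mi, x$h_in, x$h_out, x$h_joint, x$L))
  invisible(x)
}

# Fast scalar MI (standard formula) straight from phase samples.
mi_from_phases <- function(phi_out, phi_in, L) {
  bx <- wrap_bins(phi_out, L)
  by <- wrap_bins(phi_in, L)
  n <- length(bx)
  h <- function(cnt) {
    p <- cnt[cnt > 0] / n
    -sum(p * log(p))
  }
  h(tabulate(bx, L)) + h(tabulate(by, L)) -
    h(tabulate((bx - 1L) * L + by, L * L))
}
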