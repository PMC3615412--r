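#' Shuffle inter-event intervals
#'
#' Returns an event series whose inter-event intervals are a uniform random
#' permutation of the original ones. The first event time, the total span
#' (hence the last event time), the event count, and the exact interval
#' multiset are all preserved; only the serial order of intervals — and with
#' it any dependence on another series — is destroyed. This is the surrogate
#' used to build the null distribution for the mutual-information test.
#'
#' @param ev an [event_series()] with at least 3 events.
#' @return a shuffled `event_series`. Uses the current RNG stream.
#' @export
shuffle_intervals <- function(ev) {
  stopifnot(inherits(ev, "event_series"))
  if (n_events(ev) < 3) stop_insufficient("need at least 3 events to shuffle")
  iv <- diff(ev$times)
  event_series(ev$times[1] + c(0, cumsum(sample(iv))), label = ev$label)
}

#' Surrogate-test configuration
#'
#' @param n_surrogates number of surrogate replicates (>= 100); default 500.
#' @param alpha_percentile upper percentile of the surrogate distribution
#'   used as the significance cutoff, in (50, 100); default 99.
#' @param L number of bins per phase axis for mutual information; default 50.
#' @param fs_phase phase sampling rate, Hz; default 100.
#' @param seed RNG seed for the whole bootstrap (integer or NULL).
#' @return a list of class `surrogate_config`.
#' @export
surrogate_config <- function(n_surrogates = 500, alpha_percentile = 99,
                             L = 50, fs_phase = 100, seed = NULL) {
  if (n_surrogates < 100) stop_parameter("n_surrogates must be >= 100")
  if (alpha_percentile <= 50 || alpha_percentile >= 100) {
    stop_parameter("alpha_percentile must be in (50, 100)")
  }
  structure(list(n_surrogates = as.integer(n_surrogates),
                 alpha_percentile = alpha_percentile, L = as.integer(L),
                 fs_phase = fs_phase, seed = seed),
            class = "surrogate_config")
}

#' Interval-shuffling bootstrap test of phase mutual information
#'
#' Computes the observed mutual information of the instantaneous phases of
#' two event trains, then rebuilds it for `n_surrogates` replicates in which
#' the inter-event intervals of *both* trains are independently shuffled
#' before the phases are recomputed. Because shuffling preserves each
#' train's interval statistics (and the bin count and sample count are
#' unchanged), the surrogate distribution carries the same estimator bias as
#' the observed value; coupling is declared significant when the observed MI
#' exceeds the `alpha_percentile` of the surrogate distribution (one-sided,
#' distribution-free).
#'
#' @param input_ev,output_ev [event_series()] objects (>= 3 events each,
#'   overlapping spans).
#' @param cfg a [surrogate_config()].
#' @return a list of class `mi_bootstrap`: `mi_observed`, `surrogate_mi`
#'   (vector), `cutoff`, `significant`, `surrogate_mean`, `surrogate_sd`,
#'   `n_samples`, `config`.
#' @export
bootstrap_mi <- function(input_ev, output_ev, cfg = surrogate_config()) {
  stopifnot(inherits(input_ev, "event_series"),
            inherits(output_ev, "event_series"),
            inherits(cfg, "surrogate_config"))
  if (n_events(input_ev) < 3 || n_events(output_ev) < 3) {
    stop_insufficient("need at least 3 events in each series")
  }
  with_seed(cfg$seed, {
    fs <- cfg$fs_phase
    L <- cfg$L
    in_t <- input_ev$times
    out_t <- output_ev$times
    t1 <- max(in_t[1], out_t[1])
    tK <- min(in_t[length(in_t)], out_t[length(out_t)])
    if (tK <= t1) stop_insufficient("event series spans do not overlap")
    g <- phase_grid(t1, tK, fs)
    tt <- g$t
    mi_obs <- mi_from_phases(phase_at(out_t, tt), phase_at(in_t, tt), L)
    iv_in <- diff(in_t)
    iv_out <- diff(out_t)
    surr <- vapply(seq_len(cfg$n_surrogates), function(b) {
      s_in <- in_t[1] + c(0, cumsum(sample(iv_in)))
      s_out <- out_t[1] + c(0, cumsum(sample(iv_out)))
      mi_from_phases(phase_at(s_out, tt), phase_at(s_in, tt), L)
    }, numeric(1))
    cutoff <- as.numeric(stats::quantile(surr, cfg$alpha_percentile / 100,
                                         names = FALSE))
    structure(list(mi_observed = mi_obs, surrogate_mi = surr,
                   cutoff = cutoff, significant = mi_obs > cutoff,
                   surrogate_mean = mean(surr),
                   surrogate_sd = stats::sd(surr),
                   n_samples = length(tt), config = cfg),
              class = "mi_bootstrap")
  })
}

#' @export
print.mi_bootstrap <- function(x, ...) {
  cat(sprintf(paste0("MI surrogate test: observed %.4f nats vs %g%% cutoff ",
                     "%.4f (null %.4f +/- %.4f, %d surrogates) -> %s\n"),
              x$mi_observed, x$config$alpha_percentile, x$cutoff,
              x$surrogate_mean, x$surrogate_sd, x$config$n_surrogates,
              if (x$significant) "SIGNIFICANT" else "not significant"))
  invisible(x)
}

#' Classify trials by surrogate-test verdict
#'
#' Labels each trial `"non-entrained"` if its surrogate test was not
#' significant, otherwise `"entrained"`; when a reference distribution of
#' entrained MI values is supplied (e.g. from wild-type-like trials), a
#' significant trial whose MI falls below the `intermediate_quantile` of the
#' reference is labelled `"intermediate-like"` (weak but real coupling).
#'
#' @param reports list of trial results, each carrying `significant` and
#'   `mi_observed` (e.g. [bootstrap_mi()] or [run_trial()] outputs).
#' @param reference_mi optional numeric vector of reference MI values.
#' @param intermediate_quantile quantile of `reference_mi` below which a
#'   significant trial is intermediate-like; default 0.25.
#' @return a list of class `trial_classification`: `labels`,
#'   `fraction_significant`, `median_mi`, `n`.
#' @export
classify_trials <- function(reports, reference_mi = NULL,
                            intermediate_quantile = 0.25) {
  if (!length(reports)) stop_insufficient("need at least 1 report")
  get1 <- function(r, field) {
    if (!is.null(r[[field]])) r[[field]] else r$mi_test[[field]]
  }
  sig <- vapply(reports, get1, logical(1), field = "significant")
  mi <- vapply(reports, get1, numeric(1), field = "mi_observed")
  labels <- ifelse(sig, "entrained", "non-entrained")
  if (!is.null(reference_mi)) {
    q <- stats::quantile(reference_mi, intermediate_quantile, names = FALSE)
    labels[sig & mi < q] <- "intermediate-like"
  }
  structure(list(labels = labels, fraction_significant = mean(sig),
                 median_mi = stats::median(mi), n = length(sig)),
            class = "trial_classification")
}
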