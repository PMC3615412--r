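#' Per-cycle breath table
#'
#' Builds the canonical per-cycle table from paired burst onsets/offsets:
#' inspiratory duration `ti = offset - onset`, expiratory duration
#' `te = next onset - offset`, and total period `ttot = next onset - onset`.
#' The last cycle has no successor, so its `te`/`ttot` are `NA` and it is
#' excluded from period statistics downstream.
#'
#' @param onsets burst onset times, s, strictly increasing.
#' @param offsets burst offset times, s; must interleave one-per-onset
#'   (`onset < offset < next onset`).
#' @return a `data.frame` of class `breath_table` with columns
#'   `onset, offset, ti, te, ttot, is_apnea` (`is_apnea` is `NA` until
#'   [apnea_index()] is applied).
#' @export
breath_table <- function(onsets, offsets) {
  if (inherits(onsets, "simulated_trial")) {
    trial <- onsets
    offsets <- trial$output_offsets
    onsets <- trial$output_events$times
  }
  onsets <- as.numeric(onsets)
  offsets <- as.numeric(offsets)
  if (length(onsets) != length(offsets)) {
    stop_format("onsets and offsets must pair one-to-one")
  }
  n <- length(onsets)
  if (n == 0) {
    return(structure(data.frame(onset = numeric(0), offset = numeric(0),
                                ti = numeric(0), te = numeric(0),
                                ttot = numeric(0), is_apnea = logical(0)),
                     class = c("breath_table", "data.frame")))
  }
  if (any(offsets <= onsets)) stop_format("each offset must follow its onset")
  if (n > 1 && any(onsets[-1] <= offsets[-n])) {
    stop_format("onsets and offsets must interleave")
  }
  ti <- offsets - onsets
  te <- c(onsets[-1] - offsets[-n], NA_real_)
  ttot <- c(diff(onsets), NA_real_)
  structure(data.frame(onset = onsets, offset = offsets, ti = ti, te = te,
                       ttot = ttot, is_apnea = NA),
            class = c("breath_table", "data.frame"))
}

#' Detect bursts in a continuous trace by threshold crossing
#'
#' A burst onset is an upward crossing (`v[i-1] <= threshold < v[i]`), its
#' offset the subsequent downward crossing. An upward crossing within
#' `refractory` seconds of the previous offset is treated as noise ripple and
#' merged into the ongoing burst. A burst still above threshold at the end of
#' the trace is dropped. The onset/offset times reported are the times of the
#' first samples beyond each crossing.
#'
#' @param trace a [continuous_trace()].
#' @param threshold detection threshold, same units as the trace; must lie
#'   within the observed signal range.
#' @param refractory merge window after an offset, s (>= 0). Default 0.05.
#' @return a [breath_table()] (possibly with zero rows).
#' @export
detect_bursts <- function(trace, threshold, refractory = 0.05) {
  stopifnot(inherits(trace, "continuous_trace"))
  if (refractory < 0) stop_parameter("refractory must be >= 0")
  v <- trace$value
  t <- trace$time
  if (threshold < min(v) || threshold > max(v)) {
    return(breath_table(numeric(0), numeric(0)))
  }
  n <- length(v)
  up <- which(v[-1] > threshold & v[-n] <= threshold) + 1L
  down <- which(v[-1] <= threshold & v[-n] > threshold) + 1L
  ons <- t[up]
  offs <- t[down]
  offs <- offs[if (length(ons)) offs > ons[1] else FALSE]
  if (!length(ons) || !length(offs)) {
    return(breath_table(numeric(0), numeric(0)))
  }
  # drop an unterminated final burst
  if (length(ons) > length(offs)) ons <- ons[seq_along(offs)]
  # merge bursts separated by less than the refractory period
  if (length(ons) > 1) {
    gaps <- ons[-1] - offs[-length(offs)]
    keep <- gaps >= refractory
    ons <- ons[c(TRUE, keep)]
    offs <- offs[c(keep, TRUE)]
  }
  breath_table(ons, offs)
}

complete_ttot <- function(bt) bt$ttot[!is.na(bt$ttot)]

#' Respiratory pattern statistics
#'
#' Summary of the breathing pattern over an epoch: mean and SD of the total
#' cycle period, its coefficient of variation, and mean inspiratory /
#' expiratory durations. Period statistics use complete cycles only (the last
#' cycle has no successor). With `exclude_apneas = TRUE`, cycles flagged by
#' the 1.5 x mean-period rule are removed first, which isolates the
#' normocyclic variability from apnea-driven variance.
#'
#' @param bt a [breath_table()] with at least 3 complete cycles.
#' @param exclude_apneas drop apneic cycles (1.5 x rule) before computing
#'   the period statistics. Default `FALSE` (all cycles, the conventional
#'   definition).
#' @return a list of class `pattern_stats`: `mean_ttot`, `sd_ttot`,
#'   `cv_ttot`, `mean_ti`, `mean_te`, `n_cycles`.
#' @export
pattern_stats <- function(bt, exclude_apneas = FALSE) {
  stopifnot(inherits(bt, "breath_table"))
  ttot <- complete_ttot(bt)
  te <- bt$te[!is.na(bt$te)]
  ti <- bt$ti
  if (length(ttot) < 3) {
    stop_insufficient("need at least 3 complete cycles")
  }
  if (exclude_apneas) {
    flag <- ttot > 1.5 * mean(ttot)
    ttot <- ttot[!flag]
    te <- te[!flag]
  }
  structure(list(mean_ttot = mean(ttot), sd_ttot = stats::sd(ttot),
                 cv_ttot = stats::sd(ttot) / mean(ttot),
                 mean_ti = mean(ti), mean_te = mean(te),
                 n_cycles = length(ttot)),
            class = "pattern_stats")
}

#' @export
print.pattern_stats <- function(x, ...) {
  cat(sprintf(paste0("Respiratory pattern over %d cycles:\n",
                     "  Ttot %.3f +/- %.3f s (CV %.3f)\n",
                     "  Ti %.3f s, Te %.3f s\n"),
              x$n_cycles, x$mean_ttot, x$sd_ttot, x$cv_ttot,
              x$mean_ti, x$mean_te))
  invisible(x)
}

#' Apnea index
#'
#' An apnea is a respiratory cycle whose duration strictly exceeds 1.5 times
#' the mean period of the epoch (mean taken over all complete cycles,
#' apneic ones included, unless `include_apneic_in_mean = FALSE`, in which
#' case the mean is recomputed once after removing first-pass flags). The
#' index is expressed as apneas per minute of epoch.
#'
#' @param bt a [breath_table()] with at least 3 complete cycles.
#' @param epoch_duration epoch length, s (> 0).
#' @param include_apneic_in_mean keep flagged cycles in the reference mean
#'   (default `TRUE`).
#' @return a list of class `apnea_index`: `apneas_per_min`, `n_apneas`,
#'   `threshold_s`, and the logical flag vector `is_apnea` (per complete
#'   cycle).
#' @examples
#' bt <- breath_table(c(0, 0.5, 1, 1.5, 2, 3.2),
#'                    c(0, 0.5, 1, 1.5, 2, 3.2) + 0.2)
#' apnea_index(bt, epoch_duration = 3)$apneas_per_min  # 20
#' @export
apnea_index <- function(bt, epoch_duration, include_apneic_in_mean = TRUE) {
  stopifnot(inherits(bt, "breath_table"))
  if (!is.numeric(epoch_duration) || epoch_duration <= 0) {
    stop_parameter("epoch_duration must be > 0")
  }
  ttot <- complete_ttot(bt)
  if (length(ttot) < 3) stop_insufficient("need at least 3 complete cycles")
  m <- mean(ttot)
  if (!include_apneic_in_mean) {
    first_pass <- ttot > 1.5 * m
    if (any(first_pass) && !all(first_pass)) m <- mean(ttot[!first_pass])
  }
  thr <- 1.5 * m
  flag <- ttot > thr
  structure(list(apneas_per_min = 60 * sum(flag) / epoch_duration,
                 n_apneas = sum(flag), threshold_s = thr, is_apnea = flag),
            class = "apnea_index")
}

#' Inspiratory-time reduction between conditions
#'
#' Compares mean inspiratory duration (Ti) between a baseline and a
#' stimulation epoch. The percent change is
#' `100 * (mean Ti_stim - mean Ti_baseline) / mean Ti_baseline`; a negative
#' value is a reduction, the signature of an intact inspiratory off-switch
#' reflex.
#'
#' @param baseline,stim non-empty [breath_table()]s.
#' @return a list: `ti_baseline`, `ti_stim` (s), `pct_change`.
#' @export
ti_reduction <- function(baseline, stim) {
  stopifnot(inherits(baseline, "breath_table"), inherits(stim, "breath_table"))
  if (nrow(baseline) == 0 || nrow(stim) == 0) {
    stop_insufficient("both breath tables must be non-empty")
  }
  tb <- mean(baseline$ti)
  ts <- mean(stim$ti)
  list(ti_baseline = tb, ti_stim = ts,
       pct_change = 100 * (ts - tb) / tb)
}

#' Frequency-drift quality control
#'
#' A preparation fails QC when its mean respiratory period has drifted from
#' baseline by strictly more than `max_drift` (fractional change; the
#' boundary value passes).
#'
#' @param baseline,later non-empty [breath_table()]s.
#' @param max_drift maximal tolerated fractional drift; default 0.30.
#' @return a list: `pass` (logical) and `drift` (observed fraction).
#' @export
frequency_drift_qc <- function(baseline, later, max_drift = 0.30) {
  stopifnot(inherits(baseline, "breath_table"), inherits(later, "breath_table"))
  mb <- mean(complete_ttot(baseline))
  ml <- mean(complete_ttot(later))
  if (!is.finite(mb) || !is.finite(ml)) {
    stop_insufficient("both tables need at least one complete cycle")
  }
  drift <- abs(ml - mb) / mb
  list(pass = drift <= max_drift + 1e-12, drift = drift)
}

#' @rdname breath_table
#' @param bt a `breath_table`.
#' @param path file path for a TSV dump.
#' @export
write_breaths <- function(bt, path) {
  stopifnot(inherits(bt, "breath_table"))
  utils::write.table(as.data.frame(bt), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
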