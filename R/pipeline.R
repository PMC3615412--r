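#' Trial specification for the end-to-end pipeline
#'
#' Describes one analysis trial: either a simulator preset (the usual
#' validation route) or user-supplied event trains, together with every
#' analysis parameter. Defaults follow the standard protocol: 3 s coherence
#' window, 0.9 coherence threshold, 21 relative-phase bins, 50 MI bins,
#' 500 surrogates, 99th-percentile cutoff, 100 Hz phase sampling.
#'
#' @param preset a [phenotype_preset()] label or object; mutually exclusive
#'   with `input_events`/`output_events`.
#' @param params an [osc_params()] bundle (overrides `preset`'s params).
#' @param input_events,output_events [event_series()] objects for a recorded
#'   trial (stimulation epoch only).
#' @param output_offsets optional burst offset times matching
#'   `output_events` (enables Ti statistics).
#' @param baseline optional [breath_table()] of the baseline epoch for a
#'   recorded trial.
#' @param baseline_duration simulated baseline epoch length, s; default 300.
#' @param stim_duration stimulation trial length, s; default 120.
#' @param seed master RNG seed for the trial (simulation, surrogates).
#' @param fs_phase,window_w,coherence_threshold,n_bins,L,n_surrogates,
#'   alpha_percentile,fs_sig analysis parameters (see the respective
#'   functions).
#' @param trial_id identifier carried into the report.
#' @return a list of class `trial_spec`.
#' @export
trial_spec <- function(preset = NULL, params = NULL,
                       input_events = NULL, output_events = NULL,
                       output_offsets = NULL, baseline = NULL,
                       baseline_duration = 300, stim_duration = 120,
                       seed = NULL, fs_phase = 100, window_w = 3,
                       coherence_threshold = 0.9, n_bins = 21, L = 50,
                       n_surrogates = 500, alpha_percentile = 99,
                       fs_sig = 1000, trial_id = NULL) {
  label <- NULL
  if (!is.null(preset)) {
    if (is.character(preset)) preset <- phenotype_preset(preset)
    label <- preset$label
    if (is.null(params)) params <- preset$params
  }
  simulate <- is.null(input_events) || is.null(output_events)
  if (simulate && is.null(params)) {
    stop_parameter("give either a preset/params or input and output events")
  }
  structure(list(label = label %||% "custom", params = params,
                 input_events = input_events, output_events = output_events,
                 output_offsets = output_offsets, baseline = baseline,
                 baseline_duration = baseline_duration,
                 stim_duration = stim_duration, seed = seed,
                 fs_phase = fs_phase, window_w = window_w,
                 coherence_threshold = coherence_threshold,
                 n_bins = n_bins, L = L, n_surrogates = n_surrogates,
                 alpha_percentile = alpha_percentile, fs_sig = fs_sig,
                 trial_id = trial_id %||% label %||% "trial",
                 simulate = simulate),
            class = "trial_spec")
}

#' Run the full entrainment analysis for one trial
#'
#' Executes the whole chain on one trial: (simulate or take) a baseline
#' epoch and a stimulation epoch; baseline pattern statistics and apnea
#' index; Ti reduction and frequency-drift QC; instantaneous phases,
#' relative-phase histogram and Rayleigh test; windowed coherence with
#' bout/latency/slip detection; synchronization index; normalized
#' cross-correlogram (output burst envelope vs input square wave); and the
#' interval-shuffling mutual-information surrogate test. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [trial_spec()].
#' @param keep_surrogates keep the full surrogate MI vector in the report
#'   (default `FALSE`: summary only).
#' @return a list of class `coupling_report` (all metrics are plain numbers
#'   or small lists; serializable with [report_json()]).
#' @export
run_trial <- function(spec, keep_surrogates = FALSE) {
  stopifnot(inherits(spec, "trial_spec"))
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, 3L))
  if (is.null(spec$seed)) seeds <- list(NULL, NULL, NULL)

  pattern <- apnea <- ti <- drift <- NULL
  baseline_bt <- spec$baseline
  stim_start <- 0

  if (spec$simulate) {
    base_trial <- simulate_unforced_epoch(spec$params,
                                          spec$baseline_duration,
                                          seed = seeds[[1]])
    baseline_bt <- breath_table(base_trial)
    sp <- stim_params(inter_burst_freq = spec$params$omega0,
                      total_duration = spec$stim_duration)
    forced <- simulate_forced_trial(spec$params, sp, seed = seeds[[2]])
    input_ev <- forced$input_events
    output_ev <- forced$output_events
    output_off <- forced$output_offsets
    pulse_width <- sp$train_duration
    t_range <- c(0, spec$stim_duration)
  } else {
    input_ev <- spec$input_events
    output_ev <- spec$output_events
    output_off <- spec$output_offsets
    pulse_width <- attr(input_ev, "train_duration") %||% 0.1
    stim_start <- input_ev$times[1]
    t_range <- NULL
  }

  if (!is.null(baseline_bt)) {
    pattern <- pattern_stats(baseline_bt)
    apnea <- apnea_index(baseline_bt,
                         epoch_duration = if (spec$simulate) {
                           spec$baseline_duration
                         } else {
                           diff(range(baseline_bt$onset))
                         })
  }
  stim_bt <- if (!is.null(output_off)) breath_table(output_ev$times,
                                                    output_off) else NULL
  if (!is.null(baseline_bt) && !is.null(stim_bt)) {
    ti <- ti_reduction(baseline_bt, stim_bt)
    drift <- frequency_drift_qc(baseline_bt, stim_bt)
  }

  in_ps <- instantaneous_phase(input_ev, spec$fs_phase)
  out_ps <- instantaneous_phase(output_ev, spec$fs_phase)
  rp <- relative_phase(out_ps, in_ps)
  hist <- relative_phase_histogram(rp, spec$n_bins)
  ray <- rayleigh_test(rp$dphi)
  cs <- phase_coherence(rp, spec$window_w)
  bouts <- detect_bouts(cs, rp, stim_start = stim_start,
                        threshold = spec$coherence_threshold)
  sync <- synchronization_index(out_ps, in_ps)

  out_sig <- if (spec$simulate) {
    render_trace(forced, fs = spec$fs_sig, noise_sd = 0, t_range = t_range)
  } else if (!is.null(output_off)) {
    render_trace(list(output_events = output_ev, output_offsets = output_off,
                      stim = NULL),
                 fs = spec$fs_sig, noise_sd = 0)
  } else NULL
  xc <- if (!is.null(out_sig)) {
    in_sw <- square_wave(input_ev, pulse_width, fs = spec$fs_sig,
                         t_range = c(out_sig$time[1],
                                     out_sig$time[length(out_sig$time)]))
    period_guess <- if (!is.null(spec$params)) 1 / spec$params$omega0
                    else mean(diff(input_ev$times))
    normalized_cross_correlogram(out_sig, in_sw, max_lag = 2 * period_guess)
  } else NULL

  cfg <- surrogate_config(spec$n_surrogates, spec$alpha_percentile,
                          spec$L, spec$fs_phase, seed = seeds[[3]])
  boot <- bootstrap_mi(input_ev, output_ev, cfg)

  report <- list(
    trial_id = spec$trial_id, label = spec$label, seed = spec$seed,
    parameters = list(fs_phase = spec$fs_phase, window_w = spec$window_w,
                      coherence_threshold = spec$coherence_threshold,
                      n_bins = spec$n_bins, L = spec$L,
                      n_surrogates = spec$n_surrogates,
                      alpha_percentile = spec$alpha_percentile,
                      fs_sig = spec$fs_sig,
                      baseline_duration = spec$baseline_duration,
                      stim_duration = spec$stim_duration),
    pattern = if (!is.null(pattern)) {
      list(mean_ttot = pattern$mean_ttot, cv_ttot = pattern$cv_ttot,
           mean_ti = pattern$mean_ti, mean_te = pattern$mean_te,
           n_cycles = pattern$n_cycles,
           apneas_per_min = apnea$apneas_per_min)
    },
    ti_reduction = ti,
    drift_qc = drift,
    entrainment = list(
      max_rel_phase_prob = hist$max_prob,
      rayleigh_r = ray$r_bar, rayleigh_p = ray$p,
      sync_index = sync,
      latency = bouts$latency, n_bouts = bouts$n_bouts,
      mean_bout_duration = bouts$mean_bout_duration,
      total_bout_duration = bouts$total_bout_duration,
      n_slips = bouts$n_slips,
      cc_peak = if (!is.null(xc)) xc$peak else NA_real_,
      cc_peak_lag = if (!is.null(xc)) xc$peak_lag else NA_real_),
    mi_test = list(mi_observed = boot$mi_observed, cutoff = boot$cutoff,
                   significant = boot$significant,
                   surrogate_mean = boot$surrogate_mean,
                   surrogate_sd = boot$surrogate_sd),
    significant = boot$significant,
    mi_observed = boot$mi_observed
  )
  if (keep_surrogates) report$surrogate_mi <- boot$surrogate_mi
  structure(report, class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat(sprintf("Coupling report '%s' (%s):\n", x$trial_id, x$label))
  if (!is.null(x$pattern)) {
    cat(sprintf("  baseline: Ttot %.3f s, CV %.3f, %.2f apneas/min\n",
                x$pattern$mean_ttot, x$pattern$cv_ttot,
                x$pattern$apneas_per_min))
  }
  if (!is.null(x$ti_reduction)) {
    cat(sprintf("  Ti: %.3f -> %.3f s (%+.1f%%)\n",
                x$ti_reduction$ti_baseline, x$ti_reduction$ti_stim,
                x$ti_reduction$pct_change))
  }
  e <- x$entrainment
  cat(sprintf("  entrainment: sync %.3f, hist max %.3f, cc peak %.3f\n",
              e$sync_index, e$max_rel_phase_prob, e$cc_peak))
  cat(sprintf("  bouts: n %d, latency %s s, mean duration %s s, slips %s\n",
              e$n_bouts,
              if (is.na(e$latency)) "NA" else sprintf("%.1f", e$latency),
              if (is.na(e$mean_bout_duration)) "NA"
              else sprintf("%.1f", e$mean_bout_duration),
              if (is.na(e$n_slips)) "NA" else e$n_slips))
  cat(sprintf("  MI %.4f nats vs cutoff %.4f -> %s\n",
              x$mi_test$mi_observed, x$mi_test$cutoff,
              if (x$significant) "SIGNIFICANT" else "not significant"))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report a `coupling_report` or `cohort_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

trial_metric_row <- function(r) {
  e <- r$entrainment
  data.frame(trial_id = r$trial_id, label = r$label,
             cv_ttot = r$pattern$cv_ttot %||% NA_real_,
             apneas_per_min = r$pattern$apneas_per_min %||% NA_real_,
             ti_pct_change = if (!is.null(r$ti_reduction)) {
               r$ti_reduction$pct_change
             } else NA_real_,
             max_rel_phase_prob = e$max_rel_phase_prob,
             sync_index = e$sync_index,
             cc_peak = e$cc_peak,
             mi = r$mi_observed,
             significant = r$significant,
             latency = e$latency,
             mean_bout_duration = e$mean_bout_duration,
             n_slips = e$n_slips,
             stringsAsFactors = FALSE)
}

#' Run a cohort of trials and summarize by group
#'
#' Runs [run_trial()] over a list of specs with per-trial error isolation
#' (one failing trial does not abort the cohort) and aggregates the metrics
#' by phenotype label (mean, SEM, median, n). Latency is censored at the
#' stimulation duration for trials with no entrainment bout, so group
#' latency summaries remain defined when bouts are absent.
#'
#' @param specs list of [trial_spec()]s.
#' @param out_dir optional directory; when given, writes
#'   `cohort_report.json` and `trial_metrics.tsv`.
#' @param seed optional master seed; fills any spec with a `NULL` seed from
#'   a reproducible substream.
#' @return a list of class `cohort_report`: `reports` (per trial),
#'   `metrics` (data.frame), `group_summary` (data.frame), `errors`.
#' @export
run_cohort <- function(specs, out_dir = NULL, seed = NULL) {
  if (!length(specs)) stop_parameter("need at least 1 trial spec")
  if (!is.null(seed)) {
    sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      length(specs)))
    for (i in seq_along(specs)) {
      if (is.null(specs[[i]]$seed)) specs[[i]]$seed <- sub[i]
    }
  }
  reports <- vector("list", length(specs))
  errors <- list()
  for (i in seq_along(specs)) {
    reports[[i]] <- tryCatch(run_trial(specs[[i]]), error = function(e) {
      structure(list(trial_id = specs[[i]]$trial_id, label = specs[[i]]$label,
                     error = conditionMessage(e)),
                class = "trial_error")
    })
    if (inherits(reports[[i]], "trial_error")) {
      errors[[length(errors) + 1L]] <- reports[[i]]
    }
  }
  ok <- !vapply(reports, inherits, logical(1), what = "trial_error")
  if (!any(ok)) stop("all trials failed")
  metrics <- do.call(rbind, lapply(reports[ok], trial_metric_row))
  # censor undefined latencies at the stimulation duration
  stim_dur <- vapply(specs[ok], function(s) s$stim_duration, numeric(1))
  metrics$latency_censored <- ifelse(is.na(metrics$latency), stim_dur,
                                     metrics$latency)

  num_cols <- setdiff(names(metrics),
                      c("trial_id", "label", "significant"))
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  groups <- split(metrics, metrics$label)
  group_summary <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    out <- data.frame(label = g, n = nrow(df),
                      fraction_significant = mean(df$significant))
    for (cn in num_cols) {
      x <- df[[cn]]
      out[[paste0(cn, "_mean")]] <- mean(x, na.rm = TRUE)
      out[[paste0(cn, "_sem")]] <- sem(x)
      out[[paste0(cn, "_median")]] <- stats::median(x, na.rm = TRUE)
    }
    out
  }))
  res <- structure(list(reports = reports, metrics = metrics,
                        group_summary = group_summary, errors = errors),
                   class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report_json(list(group_summary = group_summary, metrics = metrics,
                     errors = errors),
                file.path(out_dir, "cohort_report.json"))
    utils::write.table(metrics, file.path(out_dir, "trial_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort of %d trials (%d failed):\n", length(x$reports),
              length(x$errors)))
  show <- c("label", "n", "fraction_significant", "cv_ttot_mean",
            "apneas_per_min_mean", "sync_index_median", "mi_median",
            "cc_peak_mean", "latency_censored_mean")
  show <- intersect(show, names(x$group_summary))
  print(x$group_summary[, show], row.names = FALSE, digits = 3)
  invisible(x)
}
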