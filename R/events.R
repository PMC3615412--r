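#' Ordered event-onset series
#'
#' An `event_series` holds the onset times (in seconds) of one rhythmic
#' process, e.g. stimulus-train onsets ("input") or burst onsets ("output").
#' Times must be finite and strictly increasing.
#'
#' @param times numeric vector of onset times, seconds.
#' @param label free-text role tag, conventionally `"input"` or `"output"`.
#' @return an object of class `event_series` with fields `times` and `label`.
#' @examples
#' ev <- event_series(c(0, 0.5, 1.0, 1.6), label = "output")
#' n_events(ev)
#' @export
event_series <- function(times, label = "output") {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop_format("event times must be finite")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop_format("event times must be strictly increasing")
  }
  structure(list(times = times, label = as.character(label)[1]),
            class = "event_series")
}

#' @rdname event_series
#' @param ev an `event_series`.
#' @export
n_events <- function(ev) length(ev$times)

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series '%s': %d events", x$label, length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" spanning [%.3f, %.3f] s", x$times[1],
                x$times[length(x$times)]))
  }
  cat(">\n")
  invisible(x)
}

#' Read / write event series as single-column delimited text
#'
#' The on-disk format is one event time (seconds) per row under a `time_s`
#' header, readable by any spreadsheet or plotting tool.
#'
#' @param path file path.
#' @param label role tag attached to the series on read.
#' @return `read_events()` returns an `event_series`; `write_events()` returns
#'   `path` invisibly.
#' @export
read_events <- function(path, label = "output") {
  df <- utils::read.delim(path)
  if (!"time_s" %in% names(df)) {
    stop_format("event file must have a 'time_s' column")
  }
  event_series(df$time_s, label = label)
}

#' @rdname read_events
#' @param ev an `event_series`.
#' @export
write_events <- function(ev, path) {
  stopifnot(inherits(ev, "event_series"))
  utils::write.table(data.frame(time_s = ev$times), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Uniformly sampled continuous trace
#'
#' Container for a continuous signal (e.g. integrated phrenic nerve activity)
#' sampled on a uniform time grid. Non-uniform sampling is rejected because
#' every downstream statistic assumes a constant step.
#'
#' @param time sample times, seconds, strictly increasing with constant step.
#' @param value signal values, arbitrary units; same length as `time`.
#' @return an object of class `continuous_trace` with fields `time`, `value`
#'   and the sampling rate `fs` (Hz).
#' @export
continuous_trace <- function(time, value) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) {
    stop_format("time and value must have equal length")
  }
  if (length(time) < 2) stop_format("trace needs at least 2 samples")
  dt <- diff(time)
  dt0 <- stats::median(dt)
  if (dt0 <= 0 || any(abs(dt - dt0) > 1e-6 * dt0)) {
    stop_format("non-uniform sampling: trace must have a constant time step")
  }
  structure(list(time = time, value = value, fs = 1 / dt0),
            class = "continuous_trace")
}

#' @export
print.continuous_trace <- function(x, ...) {
  cat(sprintf("<continuous_trace: %d samples @ %.6g Hz, [%.3f, %.3f] s>\n",
              length(x$time), x$fs, x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' @rdname continuous_trace
#' @param path file path of a two-column CSV with header `time_s,value`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop_format("trace file must have 'time_s' and 'value' columns")
  }
  continuous_trace(df$time_s, df$value)
}

#' @rdname continuous_trace
#' @param trace a `continuous_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "continuous_trace"))
  utils::write.csv(data.frame(time_s = trace$time, value = trace$value),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
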