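# Kinetic trace conditioning. The xenon strobe's flash-to-flash intensity is
# not perfectly stable, and occasional large flashes survive even the ratio
# normalization (they hit single frames, not the reference). Two-step
# treatment, mirroring the instrument's analysis chain: points that change
# faster than 5% per second relative to the last accepted value are flagged
# and replaced, then a trailing 30 s moving average smooths residual jitter.

#' Construct a kinetic trace
#'
#' @param chamber_id Chamber label.
#' @param times Strictly increasing timestamps, seconds.
#' @param values Trace values.
#' @param corrected_mask Logical vector flagging artifact-replaced points.
#' @return A `kinetic_trace` object.
#' @export
kinetic_trace <- function(chamber_id, times, values,
                          corrected_mask = rep(FALSE, length(times))) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) ||
      length(times) != length(corrected_mask)) {
    stop("times, values and corrected_mask must have equal length",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(chamber_id = as.character(chamber_id), times = times,
                 values = values, corrected_mask = as.logical(corrected_mask)),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> chamber %s, %d points (%d corrected), t = %g..%g s\n",
              x$chamber_id, length(x$times), sum(x$corrected_mask),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Flag and replace strobe artifacts in a signal trace
#'
#' A point is flagged when its relative change from the last accepted
#' (unflagged) value exceeds `max_rel_change_per_s` per second of elapsed
#' time: `|v_i - v_a| / v_a > max_rel_change_per_s * (t_i - t_a)`. Flagged
#' runs are replaced by linear interpolation between the flanking accepted
#' points (`method = "interpolate"`, default) or by holding the last
#' accepted value (`method = "hold"`). Flagged points at the end of the
#' trace, with no accepted right neighbor, hold the last accepted value.
#' The first point is always accepted. The operation is idempotent:
#' interpolated points move at exactly the chord slope that passed the
#' threshold test.
#'
#' @param series A `signal_series` or `kinetic_trace` with strictly positive
#'   values (the rule is relative; use the ratio metric).
#' @param max_rel_change_per_s Threshold as a fraction per second
#'   (default 0.05, i.e. 5%/s).
#' @param method `"interpolate"` or `"hold"`.
#' @return A `kinetic_trace` with `corrected_mask` marking replacements.
#' @export
correct_artifacts <- function(series, max_rel_change_per_s = 0.05,
                              method = c("interpolate", "hold")) {
  method <- match.arg(method)
  times <- series$times; values <- series$values
  n <- length(values)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(values <= 0)) {
    stop("values must be strictly positive for the relative-change rule",
         call. = FALSE)
  }
  flagged <- logical(n)
  last_good <- 1L
  for (i in 2:n) {
    rel <- abs(values[i] - values[last_good]) / values[last_good]
    if (rel > max_rel_change_per_s * (times[i] - times[last_good])) {
      flagged[i] <- TRUE
    } else {
      last_good <- i
    }
  }
  if (all(flagged[-1L])) {
    stop("all points after the first are flagged; trace unusable",
         call. = FALSE)
  }
  corrected <- values
  good <- which(!flagged)
  if (any(flagged)) {
    if (method == "interpolate") {
      interp <- stats::approx(times[good], values[good], xout = times[flagged],
                              rule = 2)$y
      corrected[flagged] <- interp
    } else {
      prev_good <- findInterval(which(flagged), good)
      corrected[flagged] <- values[good[pmax(prev_good, 1L)]]
    }
  }
  kinetic_trace(series$chamber_id %||% "trace", times, corrected, flagged)
}

#' Trailing moving average of a kinetic trace
#'
#' Each output value is the mean of input values with timestamps in the
#' trailing window `(t - window_s, t]`; timestamps are unchanged. The
#' window always contains the current point, so no output is empty. A
#' trailing (causal) window permits real-time readout while the assay runs.
#'
#' @param trace A `kinetic_trace`.
#' @param window_s Window length in seconds (default 30).
#' @return A smoothed `kinetic_trace` (mask preserved).
#' @export
moving_average <- function(trace, window_s = 30) {
  if (window_s < 0) stop("window_s must be >= 0", call. = FALSE)
  times <- trace$times; values <- trace$values
  n <- length(values)
  smoothed <- numeric(n)
  lo <- 1L
  csum <- cumsum(values)
  for (i in seq_len(n)) {
    while (lo < i && times[lo] <= times[i] - window_s) lo <- lo + 1L
    smoothed[i] <- (csum[i] - if (lo > 1L) csum[lo - 1L] else 0) / (i - lo + 1L)
  }
  kinetic_trace(trace$chamber_id, times, smoothed, trace$corrected_mask)
}

#' Trace value at an arbitrary time
#'
#' Linear interpolation between the bracketing samples; exact samples are
#' returned as-is. Extrapolation outside the trace's time span is an error.
#'
#' @param trace A `kinetic_trace`.
#' @param t_query Query time(s), seconds, within
#'   `[min(times), max(times)]`.
#' @return Numeric vector of interpolated values.
#' @export
value_at <- function(trace, t_query) {
  times <- trace$times
  if (any(t_query < times[1] | t_query > times[length(times)])) {
    stop(sprintf("query time outside trace range [%g, %g]",
                 times[1], times[length(times)]), call. = FALSE)
  }
  stats::approx(times, trace$values, xout = t_query)$y
}

#' Tidy data frame view of kinetic traces
#'
#' @param traces A `kinetic_trace` or list of them.
#' @return Data frame with columns `chamber_id`, `time_s`, `value`,
#'   `corrected`.
#' @export
traces_to_df <- function(traces) {
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(chamber_id = tr$chamber_id, time_s = tr$times,
               value = tr$values, corrected = tr$corrected_mask,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
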