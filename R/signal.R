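# Per-chamber signal series: a chosen color channel over time, reported raw,
# as the difference from the substrate-injection value, or as the ratio to
# it. The ratio transform is the illumination-robust metric: a static,
# chamber-position-dependent illumination factor multiplies every frame the
# same way and cancels exactly in value / value0.

.SIGNAL_CHANNELS <- c("R", "G", "B", "L", "a", "b", "h")
.SIGNAL_TRANSFORMS <- c("raw", "difference", "ratio")

#' Construct a signal series
#'
#' @param chamber_id Chamber label.
#' @param channel One of `"R"`, `"G"`, `"B"`, `"L"`, `"a"`, `"b"`, `"h"`.
#' @param transform One of `"raw"`, `"difference"`, `"ratio"`.
#' @param times Strictly increasing timestamps, seconds.
#' @param values Signal values (unitless).
#' @return A `signal_series` object; `metric` is `"<channel>:<transform>"`.
#' @export
signal_series <- function(chamber_id, channel, transform, times, values) {
  channel <- match.arg(channel, .SIGNAL_CHANNELS)
  transform <- match.arg(transform, .SIGNAL_TRANSFORMS)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(chamber_id = as.character(chamber_id),
                 channel = channel, transform = transform,
                 metric = paste(channel, transform, sep = ":"),
                 times = times, values = values),
            class = "signal_series")
}

#' @export
print.signal_series <- function(x, ...) {
  cat(sprintf("<signal_series> chamber %s, metric %s, %d points, t = %g..%g s\n",
              x$chamber_id, x$metric, length(x$times),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

# Wrap an angular difference (degrees) into (-180, 180].
.wrap_degrees <- function(d) {
  w <- (d + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Extract per-chamber signal series from a frame sequence
#'
#' For each ROI the mean chamber color is computed per frame, projected onto
#' the requested channel (RGB directly; `L`, `a`, `b`, `h` via the CIELAB
#' conversion of the mean RGB), and transformed relative to the reference
#' value `value0`, the mean of the first `n_ref` frames at or after
#' `reference_time` (the moment TMB enters the chamber). Averaging a few
#' frames suppresses single-frame strobe jitter in the denominator.
#'
#' Hue is angular: its `difference` transform is the wrapped difference in
#' (-180, 180\], and its `ratio` transform divides the reference-unwrapped
#' hue (`value0 + wrapped difference`) by `value0`, avoiding the 0/360
#' branch cut.
#'
#' @param frames A `frame_sequence`.
#' @param rois An `roi_set` (or single `chamber_roi`).
#' @param channel Color channel, see [signal_series()].
#' @param transform `"raw"`, `"difference"`, or `"ratio"`.
#' @param reference_time Seconds; must lie within the sequence time span.
#' @param n_ref Number of frames averaged into `value0` (default 3).
#' @return Named list of `signal_series`, one per chamber.
#' @export
build_series <- function(frames, rois, channel = "R", transform = "ratio",
                         reference_time = 0, n_ref = 3L) {
  channel <- match.arg(channel, .SIGNAL_CHANNELS)
  transform <- match.arg(transform, .SIGNAL_TRANSFORMS)
  times <- frame_times(frames)
  if (reference_time < times[1] || reference_time > times[length(times)]) {
    stop("reference_time outside the sequence time span", call. = FALSE)
  }
  ref_idx <- which(times >= reference_time)
  ref_idx <- ref_idx[seq_len(min(n_ref, length(ref_idx)))]

  rois <- as.data.frame(rois)
  out <- vector("list", nrow(rois))
  names(out) <- rois$chamber_id
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, , drop = FALSE]
    rgb <- t(vapply(frames, roi_mean, numeric(3), roi = roi))
    vals <- switch(channel,
      R = rgb[, 1L], G = rgb[, 2L], B = rgb[, 3L],
      {
        lab <- xyz_to_lab(rgb_to_xyz(rgb))
        lab[, channel]
      })
    if (channel == "h" && anyNA(vals)) {
      stop(sprintf("chamber '%s' has achromatic frames; hue undefined",
                   roi$chamber_id), call. = FALSE)
    }
    v0 <- mean(vals[ref_idx])
    tr <- switch(transform,
      raw = vals,
      difference = if (channel == "h") .wrap_degrees(vals - v0) else vals - v0,
      ratio = {
        if (v0 == 0) {
          stop(sprintf("chamber '%s': reference value is zero; ratio undefined",
                       roi$chamber_id), call. = FALSE)
        }
        if (channel == "h") (v0 + .wrap_degrees(vals - v0)) / v0 else vals / v0
      })
    out[[i]] <- signal_series(roi$chamber_id, channel, transform, times, tr)
  }
  out
}

#' Tidy data frame view of signal series
#'
#' @param series A `signal_series` or list of them.
#' @return Data frame with columns `chamber_id`, `time_s`, `metric`,
#'   `value`.
#' @export
signals_to_df <- function(series) {
  if (inherits(series, "signal_series")) series <- list(series)
  do.call(rbind, lapply(series, function(s) {
    data.frame(chamber_id = s$chamber_id, time_s = s$times,
               metric = s$metric, value = s$values,
               stringsAsFactors = FALSE)
  }))
}

#' @export
as.data.frame.signal_series <- function(x, ...) signals_to_df(x)

#' Write signal series to a tidy CSV
#'
#' Columns `chamber_id,time_s,metric,value`.
#'
#' @param series A `signal_series` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(series, path) {
  utils::write.csv(signals_to_df(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy signal CSV back into signal series
#'
#' @param path CSV written by [write_signals()].
#' @return Named list of `signal_series` keyed by
#'   `"<chamber_id>|<metric>"`.
#' @export
read_signals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("chamber_id", "time_s", "metric", "value")
  if (!all(needed %in% names(df))) {
    stop("signal CSV must have columns chamber_id,time_s,metric,value",
         call. = FALSE)
  }
  keys <- paste(df$chamber_id, df$metric, sep = "|")
  out <- lapply(split(df, keys), function(d) {
    d <- d[order(d$time_s), ]
    parts <- strsplit(d$metric[1], ":", fixed = TRUE)[[1]]
    signal_series(d$chamber_id[1], parts[1], parts[2], d$time_s, d$value)
  })
  out
}
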