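# Calibration: signal vs log10(concentration) ordinary least squares over
# the nonzero standards, evaluated either at a single read time or along a
# time grid (the R^2 trajectory). The blank (0 ng/mL) cannot enter the log
# fit; it supplies the limit of detection via the blank +/- 3 SD convention.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean. Used
#' as the concordance criterion between replicate chips.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return CV as a fraction (0.02 = 2%).
#' @examples
#' coefficient_of_variation(c(5.071, 4.984, 5.056, 5.011))  # ~0.008
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  stats::sd(values) / m
}

#' Read a standards table
#'
#' CSV with header `chamber_id,concentration_ng_per_ml`.
#'
#' @param path CSV path.
#' @return Data frame with those two columns.
#' @export
read_standards <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("chamber_id", "concentration_ng_per_ml") %in% names(df))) {
    stop("standards CSV needs columns chamber_id,concentration_ng_per_ml",
         call. = FALSE)
  }
  if (any(df$concentration_ng_per_ml < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  df$chamber_id <- as.character(df$chamber_id)
  df
}

#' Fit a log-linear calibration curve
#'
#' Ordinary least squares of signal on log10(concentration) over the
#' nonzero standards; the blank is excluded (log10(0) undefined) and used
#' only by [estimate_lod()]. R^2 is 1 - SS_res / SS_tot, so a fit to
#' signals with zero variance is reported as degenerate (R^2 `NA`) rather
#' than silently perfect.
#'
#' @param standards Data frame `chamber_id`, `concentration_ng_per_ml`
#'   (see [read_standards()]).
#' @param signals Named numeric vector of signals keyed by chamber id.
#' @param t_read Read time in seconds (metadata, default `NA`).
#' @param metric Metric label (metadata, default `NA`).
#' @return A `calibration_model`: list with `t_read`, `slope` (signal per
#'   log10 ng/mL), `intercept`, `r_squared`, `metric`, `n`, `degenerate`.
#' @export
fit_calibration <- function(standards, signals, t_read = NA_real_,
                            metric = NA_character_) {
  nz <- standards[standards$concentration_ng_per_ml > 0, , drop = FALSE]
  if (length(unique(nz$concentration_ng_per_ml)) < 3L) {
    stop("need at least 3 distinct nonzero standard concentrations",
         call. = FALSE)
  }
  missing <- setdiff(nz$chamber_id, names(signals))
  if (length(missing)) {
    stop(sprintf("no signal for standard chamber(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- log10(nz$concentration_ng_per_ml)
  y <- as.numeric(signals[nz$chamber_id])
  if (anyNA(y)) stop("NA signal among standards", call. = FALSE)
  degenerate <- stats::var(y) == 0
  if (degenerate) {
    slope <- 0; intercept <- y[1]; r2 <- NA_real_
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  }
  structure(list(t_read = t_read, slope = slope, intercept = intercept,
                 r_squared = r2, metric = metric, n = length(y),
                 degenerate = degenerate),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> t_read = %s s: signal = %.5g + %.5g * log10(c), R^2 = %s%s\n",
    format(x$t_read), x$intercept, x$slope,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' R^2 trajectory of time-resolved calibration curves
#'
#' Refits the calibration at every grid time, reading each standard's
#' smoothed trace with [value_at()]. Grid times where the fit fails are
#' reported with `NA` and a warning naming the time point.
#'
#' @param traces Named list of `kinetic_trace` keyed by chamber id
#'   (standards, already corrected and smoothed).
#' @param standards Standards table.
#' @param time_grid Seconds; every trace must cover the grid.
#' @return Data frame `time_s`, `r_squared`, `slope`, `intercept`.
#' @export
r2_trajectory <- function(traces, standards, time_grid) {
  nz_ids <- standards$chamber_id[standards$concentration_ng_per_ml > 0]
  missing <- setdiff(nz_ids, names(traces))
  if (length(missing)) {
    stop(sprintf("no trace for standard chamber(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(time_s = time_grid, r_squared = NA_real_,
                    slope = NA_real_, intercept = NA_real_)
  for (i in seq_along(time_grid)) {
    tq <- time_grid[i]
    sig <- vapply(traces[nz_ids], value_at, numeric(1), t_query = tq)
    names(sig) <- nz_ids
    model <- tryCatch(fit_calibration(standards, sig, t_read = tq),
                      error = function(e) {
                        warning(sprintf("fit failed at t = %g s: %s", tq,
                                        conditionMessage(e)), call. = FALSE)
                        NULL
                      })
    if (!is.null(model) && !model$degenerate) {
      out$r_squared[i] <- model$r_squared
      out$slope[i] <- model$slope
      out$intercept[i] <- model$intercept
    }
  }
  out
}

#' Earliest sustained-reliability read time
#'
#' Smallest grid time whose R^2 meets the threshold *and* stays at or above
#' it for every later grid time. A single-point crossing does not qualify:
#' image-analysis values fluctuate, so reliability must be sustained.
#' Absence of any such time is a valid result, returned as `NA`.
#'
#' @param r2_series Data frame with `time_s` and `r_squared` (as from
#'   [r2_trajectory()]), or a numeric R^2 vector with `times` supplied.
#' @param threshold R^2 threshold (default 0.95).
#' @param times Timestamps when `r2_series` is a bare numeric vector.
#' @return Time in seconds, or `NA_real_` when never sustained.
#' @export
earliest_reliable_time <- function(r2_series, threshold = 0.95, times = NULL) {
  if (is.data.frame(r2_series)) {
    times <- r2_series$time_s
    r2 <- r2_series$r_squared
  } else {
    r2 <- as.numeric(r2_series)
    if (is.null(times)) stop("supply times with a bare R^2 vector",
                             call. = FALSE)
  }
  if (!length(r2)) stop("empty R^2 series", call. = FALSE)
  ok <- !is.na(r2) & r2 >= threshold
  sustained <- rev(cumprod(rev(ok))) > 0
  if (!any(sustained)) return(NA_real_)
  times[which(sustained)[1]]
}

#' Limit of detection from blank replicates
#'
#' Inverts the calibration curve at the blank mean plus or minus
#' `k` standard deviations, the sign chosen toward increasing
#' concentration: minus for a decreasing-signal metric (negative slope,
#' e.g. the red ratio), plus for an increasing one.
#'
#' @param model A `calibration_model` with nonzero slope.
#' @param blank_signals Numeric vector of >= 2 blank (0 ng/mL) replicate
#'   signals.
#' @param k SD multiplier (default 3).
#' @return An `lod_estimate`: list with `lod` (ng/mL), `blank_mean`,
#'   `blank_sd`, `k`.
#' @export
estimate_lod <- function(model, blank_signals, k = 3) {
  if (length(blank_signals) < 2L) {
    stop("need at least 2 blank replicates", call. = FALSE)
  }
  if (is.na(model$slope) || abs(model$slope) < .Machine$double.eps^0.5) {
    stop("slope is ~0; LOD undefined", call. = FALSE)
  }
  m <- mean(blank_signals)
  s <- stats::sd(blank_signals)
  y_crit <- m + ifelse(model$slope > 0, 1, -1) * k * s
  lod <- 10^((y_crit - model$intercept) / model$slope)
  structure(list(lod = lod, blank_mean = m, blank_sd = s, k = k),
            class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat(sprintf("<lod_estimate> LOD = %.4g ng/mL (blank %.5g +/- %.3g, k = %g)\n",
              x$lod, x$blank_mean, x$blank_sd, x$k))
  invisible(x)
}

#' Rank candidate signal metrics against reference optical densities
#'
#' Reproduces the metric-selection screen run on replicate chips: the chip
#' whose reference OD deviates most from the mean of the others is the
#' "discordant" chip; the remaining chips form the concordant subset. A
#' metric passes when (a) its CV over the concordant subset is below
#' `cv_max` and (b) it singles out the same discordant chip as the ODs do
#' (sign-free: a decreasing metric such as the red ratio legitimately
#' anticorrelates with OD).
#'
#' @param metric_signals Named list: one named numeric vector of endpoint
#'   signals per metric, keyed by chip id.
#' @param reference Data frame `chip_id`, `od` (see the
#'   `chip_id,od` CSV interface), or a named numeric vector of ODs.
#' @param cv_max CV bound (default 0.02).
#' @return Data frame per metric: `metric`, `evaluable`, `cv`, `cv_pass`,
#'   `trend_pass`, `pass`; attribute `"discordant_chip"` names the OD
#'   outlier.
#' @export
compare_metrics <- function(metric_signals, reference, cv_max = 0.02) {
  if (is.data.frame(reference)) {
    ods <- stats::setNames(reference$od, reference$chip_id)
  } else {
    ods <- reference
  }
  if (length(ods) < 3L) stop("need at least 3 reference chips", call. = FALSE)
  dev_od <- vapply(seq_along(ods),
                   function(i) abs(ods[i] - mean(ods[-i])), numeric(1))
  discordant <- names(ods)[which.max(dev_od)]
  concordant <- setdiff(names(ods), discordant)

  rows <- lapply(names(metric_signals), function(metric) {
    sig <- metric_signals[[metric]]
    if (!all(names(ods) %in% names(sig)) || anyNA(sig[names(ods)])) {
      return(data.frame(metric = metric, evaluable = FALSE, cv = NA_real_,
                        cv_pass = NA, trend_pass = NA, pass = FALSE))
    }
    sig <- sig[names(ods)]
    cv <- coefficient_of_variation(sig[concordant])
    dev_m <- vapply(seq_along(sig),
                    function(i) abs(sig[i] - mean(sig[-i])), numeric(1))
    trend <- names(sig)[which.max(dev_m)] == discordant
    data.frame(metric = metric, evaluable = TRUE, cv = cv,
               cv_pass = cv < cv_max, trend_pass = trend,
               pass = cv < cv_max && trend)
  })
  out <- do.call(rbind, rows)
  attr(out, "discordant_chip") <- discordant
  out
}
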