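# Independent oracles used to cross-check the implementation. Each is a
# deliberately plain, scalar transcription of the underlying math, kept
# structurally separate from the package's vectorized code paths.

# Scalar RGB -> CIELAB reference: same 3x3 matrix, same white point, no
# gamma, standard CIE piecewise companding. One pixel at a time.
oracle_rgb_to_lab <- function(r, g, b) {
  X <- 0.4124 * r + 0.3576 * g + 0.1805 * b
  Y <- 0.2126 * r + 0.7152 * g + 0.0722 * b
  Z <- 0.0193 * r + 0.1192 * g + 0.9505 * b
  f <- function(x) {
    if (x > (24 / 116)^3) x^(1 / 3) else (841 / 108) * x + 16 / 116
  }
  fx <- f(X / 0.9505); fy <- f(Y / 1.0); fz <- f(Z / 1.089)
  c(L = 116 * fy - 16,
    a = 500 * (fx - fy),
    b = 200 * (fy - fz))
}

# Brute-force circular-ROI mean: loop over every pixel of the frame.
oracle_roi_mean <- function(image, center_row, center_col, radius) {
  h <- dim(image)[1]; w <- dim(image)[2]
  acc <- c(0, 0, 0); n <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if ((i - 1 - center_row)^2 + (j - 1 - center_col)^2 <= radius^2) {
        acc <- acc + image[i, j, 1:3]
        n <- n + 1L
      }
    }
  }
  acc / n
}

# Closed-form simple-OLS via the normal equations, plus R^2.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Closed-form LOD inversion of a log-linear curve at blank mean -/+ k sd
# (sign toward increasing concentration).
oracle_lod <- function(slope, intercept, blanks, k = 3) {
  m <- mean(blanks); s <- sd(blanks)
  y <- if (slope > 0) m + k * s else m - k * s
  10^((y - intercept) / slope)
}

# Small two-chamber geometry used by several illumination tests.
twin_chamber_config <- function(...) {
  synthetic_config(
    frame_height = 40, frame_width = 90,
    rois = roi_set(chamber_roi("twin_a", 20, 22, 6),
                   chamber_roi("twin_b", 20, 66, 6)),
    standards = c(twin_a = 100, twin_b = 100),
    illumination = c(1.0, 0.7),
    jitter_sd = 0, flash_prob = 0, pixel_noise_sd = 0,
    ...
  )
}

# Standards table matching a synthetic config.
standards_table <- function(config) {
  data.frame(chamber_id = names(config$standards),
             concentration_ng_per_ml = unname(config$standards),
             stringsAsFactors = FALSE)
}

# Run correction + smoothing + fit on one generated assay; returns the
# pieces the calibration-recovery tests need.
analyze_assay <- function(config, grid_step = 5) {
  assay <- generate_assay(config)
  series <- build_series(assay$frames, config$rois, "R", "ratio")
  traces <- lapply(series, function(s) moving_average(correct_artifacts(s)))
  std <- standards_table(config)
  ts <- saturation_time(config)
  sig <- vapply(traces, value_at, numeric(1), t_query = ts)
  model <- fit_calibration(std, sig, t_read = ts, metric = "R:ratio")
  grid <- seq(0, config$duration_s, by = grid_step)
  r2 <- r2_trajectory(traces, std, grid)
  list(assay = assay, traces = traces, standards = std, model = model,
       r2 = r2, signals = sig)
}
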