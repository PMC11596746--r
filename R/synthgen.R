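# Synthetic assay-image generator. Emulates the strobe-imaged disk: circular
# reaction chambers whose color develops from colorless toward blue (red
# channel falling, blue constant) at a concentration-dependent rate, under a
# static chamber-position illumination factor (lateral light source) and
# per-frame multiplicative strobe jitter with occasional large flashes.
# Ground truth (noise-free ratio traces, illumination factors, jitter and
# flash schedule) is returned alongside the frames so every pipeline stage
# can be tested without instrument data.
#
# Kinetic model: red ratio(t) = 1 - A(c) * (1 - exp(-k t)) with Langmuir
# dose dependence A(c) = A_max * c / (c + c50) — the simplest saturating
# form with fast early change, stable concentration ordering and
# red-channel specificity.

#' Configuration for a synthetic assay
#'
#' Defaults describe the reference simulated assay: five chambers holding
#' the standard series 0/1/10/100/1000 ng/mL, one frame per second for
#' 180 s, saturating-exponential kinetics (rate 1/60 per s, so development
#' is 95% complete at 180 s), Langmuir dose response (`a_max` 0.25,
#' `c50` 50 ng/mL), a lateral-illumination gradient of static factors from
#' 1.00 down to 0.72 across chamber positions, 1% per-frame strobe jitter,
#' 8% flash probability with amplitudes uniform in 0.10-0.30, and pixel
#' noise sd 0.008 (about 2 8-bit counts).
#'
#' @param frame_height,frame_width Frame size in pixels.
#' @param rois `roi_set` of chamber geometries (defaults to five chambers
#'   of radius 7 in a row).
#' @param standards Named numeric vector chamber_id -> ng/mL.
#' @param frame_interval_s,duration_s Sampling interval and run length.
#' @param a_max Maximum fractional red-channel drop, in \[0, 1).
#' @param c50 Half-saturation concentration, ng/mL.
#' @param rate_k Kinetic rate constant, per second.
#' @param green_fraction Green drop as a fraction of the red drop.
#' @param base_rgb Colorless-chamber RGB on the \[0, 1\] scale.
#' @param background Background gray level.
#' @param illumination Per-chamber static illumination factors in (0, 1\].
#' @param jitter_sd Per-frame multiplicative jitter sd.
#' @param flash_prob Per-frame probability of a large flash.
#' @param flash_amp_range Flash amplitude range (fractional brightness
#'   excursion), used as `1 + U(range)`.
#' @param pixel_noise_sd Additive Gaussian pixel noise sd (on \[0, 1\]).
#' @param quantize Quantize frames to 8 bits in memory (PNG output is
#'   always 8-bit); default `FALSE` so noise-free runs are exact.
#' @param draw_margin_px Chamber disks are drawn this much larger than the
#'   analysis ROI so mask edges do not touch background.
#' @param seed Integer seed; fixes the full output.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(frame_height = 48, frame_width = 200,
                             rois = NULL,
                             standards = c(chamber_1 = 0, chamber_2 = 1,
                                           chamber_3 = 10, chamber_4 = 100,
                                           chamber_5 = 1000),
                             frame_interval_s = 1, duration_s = 180,
                             a_max = 0.25, c50 = 50, rate_k = 1 / 60,
                             green_fraction = 0.5,
                             base_rgb = c(0.82, 0.82, 0.82),
                             background = 0.5,
                             illumination = NULL,
                             jitter_sd = 0.01, flash_prob = 0.08,
                             flash_amp_range = c(0.10, 0.30),
                             pixel_noise_sd = 0.008,
                             quantize = FALSE,
                             draw_margin_px = 2,
                             seed = 1L) {
  n_chambers <- length(standards)
  if (is.null(rois)) {
    cols <- seq(20, frame_width - 20, length.out = n_chambers)
    rois <- do.call(roi_set, lapply(seq_len(n_chambers), function(i) {
      chamber_roi(names(standards)[i], frame_height / 2, cols[i], 7)
    }))
  }
  if (is.null(illumination)) {
    illumination <- seq(1.0, 0.72, length.out = n_chambers)
  }
  if (!setequal(rois$chamber_id, names(standards))) {
    stop("rois and standards must reference the same chamber ids",
         call. = FALSE)
  }
  stopifnot(all(standards >= 0), !is.null(names(standards)),
            a_max >= 0, a_max < 1, c50 > 0, rate_k > 0,
            green_fraction >= 0, green_fraction <= 1,
            all(base_rgb > 0), all(base_rgb <= 1),
            all(illumination > 0), all(illumination <= 1),
            jitter_sd >= 0, flash_prob >= 0, flash_prob <= 1,
            length(flash_amp_range) == 2, all(flash_amp_range >= 0),
            pixel_noise_sd >= 0, frame_interval_s > 0, duration_s > 0)
  # drawn disks (ROI + margin) must stay inside the frame and disjoint
  grown <- rois
  grown$radius <- grown$radius + draw_margin_px
  do.call(roi_set, list(as.data.frame(grown)))
  for (i in seq_len(nrow(grown))) {
    .roi_pixels(grown[i, , drop = FALSE], c(frame_height, frame_width))
  }
  structure(list(frame_height = frame_height, frame_width = frame_width,
                 rois = rois, standards = standards,
                 frame_interval_s = frame_interval_s, duration_s = duration_s,
                 a_max = a_max, c50 = c50, rate_k = rate_k,
                 green_fraction = green_fraction, base_rgb = base_rgb,
                 background = background,
                 illumination = stats::setNames(illumination,
                                                rois$chamber_id),
                 jitter_sd = jitter_sd, flash_prob = flash_prob,
                 flash_amp_range = flash_amp_range,
                 pixel_noise_sd = pixel_noise_sd, quantize = quantize,
                 draw_margin_px = draw_margin_px,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Noise-free red-channel ratio trace for one concentration.
.ratio_trace <- function(config, conc, times) {
  a <- config$a_max * conc / (conc + config$c50)
  1 - a * (1 - exp(-config$rate_k * times))
}

#' Time at which color development is effectively saturated
#'
#' Three kinetic time constants (95% of the asymptotic drop), capped at the
#' run length.
#'
#' @param config A `synthetic_config`.
#' @return Seconds.
#' @export
saturation_time <- function(config) {
  min(3 / config$rate_k, config$duration_s)
}

#' The generator's own log-linear calibration slope
#'
#' OLS slope of the noise-free red-ratio signal at time `t` against
#' log10(concentration) over the nonzero standards — the reference value a
#' fitted calibration should recover.
#'
#' @param config A `synthetic_config`.
#' @param t Read time, seconds (default [saturation_time()]).
#' @return Slope in ratio units per log10(ng/mL) (negative).
#' @export
generator_loglinear_slope <- function(config, t = saturation_time(config)) {
  conc <- config$standards[config$standards > 0]
  y <- vapply(conc, function(cc) .ratio_trace(config, cc, t), numeric(1))
  x <- log10(conc)
  unname(stats::cov(x, y) / stats::var(x))
}

# Run code with a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-frame multiplicative strobe factors and the flash schedule.
.jitter_sequence <- function(config, n) {
  jitter <- 1 + stats::rnorm(n, 0, config$jitter_sd)
  is_flash <- stats::runif(n) < config$flash_prob
  is_flash[1] <- FALSE  # the reference frame itself is never a flash
  amps <- numeric(n)
  amps[is_flash] <- stats::runif(sum(is_flash), config$flash_amp_range[1],
                                 config$flash_amp_range[2])
  list(jitter = jitter * (1 + amps), flash_frames = which(is_flash),
       flash_amplitudes = amps[is_flash])
}

#' Generate a synthetic assay image sequence with ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `frames` (a `frame_sequence`) and `truth` (a
#'   `synthetic_truth`: per-chamber concentration, illumination factor and
#'   noise-free ratio trace, plus the global jitter sequence and flash
#'   frame indices, and the generating config).
#' @export
generate_assay <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  times <- seq(0, config$duration_s, by = config$frame_interval_s)
  n <- length(times)
  h <- config$frame_height; w <- config$frame_width
  rois <- config$rois

  draw <- rois
  draw$radius <- draw$radius + config$draw_margin_px
  pix <- lapply(seq_len(nrow(draw)), function(i) {
    px <- .roi_pixels(draw[i, , drop = FALSE], c(h, w))
    cbind(px[, "row"] + 1L, px[, "col"] + 1L)
  })
  names(pix) <- draw$chamber_id

  ratio_traces <- lapply(config$standards, function(cc) {
    .ratio_trace(config, cc, times)
  })

  .with_seed(config$seed, {
    js <- .jitter_sequence(config, n)
    frames <- vector("list", n)
    npx <- h * w
    for (fi in seq_len(n)) {
      img <- array(config$background * js$jitter[fi], dim = c(h, w, 3))
      for (ci in seq_along(pix)) {
        id <- names(pix)[ci]
        red <- ratio_traces[[id]][fi]
        chan <- c(red,
                  1 - config$green_fraction * (1 - red),
                  1)
        val <- config$base_rgb * chan * config$illumination[[id]] *
          js$jitter[fi]
        idx <- pix[[ci]]
        for (k in 1:3) {
          plane <- img[, , k]
          plane[idx] <- val[k]
          img[, , k] <- plane
        }
      }
      if (config$pixel_noise_sd > 0) {
        img <- img + stats::rnorm(3 * npx, 0, config$pixel_noise_sd)
      }
      img[img < 0] <- 0
      img[img > 1] <- 1
      if (config$quantize) img <- round(img * 255) / 255
      frames[[fi]] <- frame_record(times[fi], img)
    }
    truth <- structure(list(
      times = times,
      chambers = lapply(stats::setNames(names(config$standards),
                                        names(config$standards)),
                        function(id) {
        list(chamber_id = id,
             concentration_ng_per_ml = unname(config$standards[[id]]),
             illumination = unname(config$illumination[[id]]),
             ratio_trace = ratio_traces[[id]])
      }),
      jitter = js$jitter,
      flash_frames = js$flash_frames,
      flash_amplitudes = js$flash_amplitudes,
      config = config
    ), class = "synthetic_truth")
    list(frames = frame_sequence(frames), truth = truth)
  })
}

#' Simulate chamber-level ratio traces (no image rendering)
#'
#' Fast trace-level counterpart of [generate_assay()]: the observed ratio
#' series a chamber would yield after ROI averaging and ratio
#' normalization, i.e. `ratio(t) * jitter(t) / value0` with `value0` the
#' mean of the first `n_ref` jittered samples (static illumination cancels
#' identically and is omitted). No clipping or pixel noise is applied.
#' Used to study the artifact-correction and smoothing stages against the
#' noise-free truth.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed (default `config$seed`).
#' @param n_ref Frames averaged into the reference value (default 3).
#' @return List with `times`, `flash_frames`, `jitter`, and per chamber
#'   (named list `chambers`): `clean` (noise-free normalized trace) and
#'   `observed`.
#' @export
simulate_ratio_traces <- function(config, seed = config$seed, n_ref = 3L) {
  times <- seq(0, config$duration_s, by = config$frame_interval_s)
  n <- length(times)
  .with_seed(seed, {
    js <- .jitter_sequence(config, n)
    ref <- seq_len(min(n_ref, n))
    chambers <- lapply(stats::setNames(names(config$standards),
                                       names(config$standards)),
                       function(id) {
      clean <- .ratio_trace(config, config$standards[[id]], times)
      raw <- clean * js$jitter
      list(chamber_id = id,
           concentration_ng_per_ml = unname(config$standards[[id]]),
           clean = clean / mean(clean[ref]),
           observed = raw / mean(raw[ref]))
    })
    list(times = times, chambers = chambers,
         flash_frames = js$flash_frames, jitter = js$jitter)
  })
}

#' Write a synthetic assay to a fixture directory
#'
#' Layout: `frames/frame_%04d.png` (or `.jpg` in JPEG mode),
#' `manifest.csv`, `rois.yaml`, `standards.csv`, `truth.json`. PNG is
#' lossless, so [read_frame_sequence()] round-trips the 8-bit fixture
#' exactly; JPEG mode (requires EBImage) emulates the instrument's capture
#' format.
#'
#' @param frames A `frame_sequence`.
#' @param truth The matching `synthetic_truth`.
#' @param directory Output directory (created if needed).
#' @param format `"png"` or `"jpeg"`.
#' @param quality JPEG quality (ignored for PNG).
#' @return `directory`, invisibly.
#' @export
write_fixture <- function(frames, truth, directory, format = c("png", "jpeg"),
                          quality = 95) {
  format <- match.arg(format)
  frame_dir <- file.path(directory, "frames")
  dir.create(frame_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(frame_dir)) {
    stop(sprintf("cannot create fixture directory: %s", directory),
         call. = FALSE)
  }
  ext <- if (format == "png") "png" else "jpg"
  fnames <- sprintf("frames/frame_%04d.%s", seq_along(frames), ext)
  for (i in seq_along(frames)) {
    img <- frames[[i]]$image
    path <- file.path(directory, fnames[i])
    if (format == "png") {
      png::writePNG(img, path)
    } else {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("JPEG fixtures require the EBImage package", call. = FALSE)
      }
      EBImage::writeImage(EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                         colormode = "Color"),
                          path, quality = quality)
    }
  }
  utils::write.csv(data.frame(filename = fnames,
                              time_s = frame_times(frames)),
                   file.path(directory, "manifest.csv"), row.names = FALSE)
  config <- truth$config
  write_rois(config$rois, file.path(directory, "rois.yaml"))
  utils::write.csv(data.frame(chamber_id = names(config$standards),
                              concentration_ng_per_ml =
                                unname(config$standards)),
                   file.path(directory, "standards.csv"), row.names = FALSE)
  truth_json <- list(
    times = truth$times,
    chambers = lapply(truth$chambers, function(ch) {
      list(chamber_id = ch$chamber_id,
           concentration_ng_per_ml = ch$concentration_ng_per_ml,
           illumination = ch$illumination,
           ratio_trace = ch$ratio_trace)
    }),
    jitter = truth$jitter,
    flash_frames = truth$flash_frames,
    flash_amplitudes = truth$flash_amplitudes,
    seed = config$seed
  )
  jsonlite::write_json(truth_json, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}
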