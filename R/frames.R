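# Frame-sequence I/O. A frame sequence is the ordered list of strobe images
# of the rotating disk, each tagged with seconds since assay start. Frames
# are held as H x W x 3 numeric arrays in [0, 1] (8-bit value / 255).

#' Construct a single timestamped frame
#'
#' @param t Seconds since assay start (>= 0).
#' @param image H x W x 3 numeric array with values in \[0, 1\].
#' @return A `frame_record` object.
#' @export
frame_record <- function(t, image) {
  t <- as.numeric(t)
  if (length(t) != 1L || is.na(t) || t < 0) {
    stop("t must be a single non-negative number", call. = FALSE)
  }
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L) {
    stop("image must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(image)[3L] > 3L) image <- image[, , 1:3, drop = FALSE]
  structure(list(t = t, image = image), class = "frame_record")
}

#' Assemble frames into a time-ordered sequence
#'
#' @param frames List of [frame_record()] objects sharing dimensions.
#' @return A `frame_sequence` (list of frames sorted by time) with a `dim`
#'   attribute `c(H, W)`.
#' @export
frame_sequence <- function(frames) {
  if (length(frames) == 0L) stop("empty frame sequence", call. = FALSE)
  times <- vapply(frames, function(f) f$t, numeric(1))
  frames <- frames[order(times)]
  times <- sort(times)
  if (any(diff(times) <= 0)) {
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  }
  dims <- vapply(frames, function(f) dim(f$image)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  structure(frames, class = "frame_sequence", frame_dim = dims[, 1])
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- attr(x, "frame_dim")
  cat(sprintf("<frame_sequence> %d frames, %d x %d px, t = %g..%g s\n",
              length(x), d[1], d[2], x[[1]]$t, x[[length(x)]]$t))
  invisible(x)
}

#' Times of a frame sequence
#' @param frames A `frame_sequence`.
#' @return Numeric vector of timestamps in seconds.
#' @export
frame_times <- function(frames) {
  vapply(frames, function(f) f$t, numeric(1))
}

#' Read one raster image as an RGB array
#'
#' PNG and TIFF are read natively; JPEG (the instrument's capture format)
#' requires the EBImage package. Alpha channels are dropped and grayscale
#' images rejected.
#'
#' @param path Path to a .png, .tif(f), .jpg or .jpeg file.
#' @return H x W x 3 numeric array in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("reading JPEG frames requires the EBImage package", call. = FALSE)
      }
      # EBImage stores x (column) first; transpose to row-major H x W x C
      aperm(EBImage::imageData(EBImage::readImage(path)), c(2L, 1L, 3L))
    },
    stop(sprintf("unsupported image format '%s': %s", ext, path),
         call. = FALSE)
  )
  if (length(dim(img)) != 3L || dim(img)[3L] < 3L) {
    stop(sprintf("not an RGB image: %s", path), call. = FALSE)
  }
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Read a timestamped frame sequence from disk
#'
#' The manifest is a CSV with header `filename,time_s`; filenames are
#' resolved relative to `directory`. Frames are returned sorted by
#' timestamp regardless of manifest order.
#'
#' @param directory Directory containing the frame images.
#' @param manifest_path Path to the manifest CSV (default
#'   `manifest.csv` inside `directory`).
#' @return A `frame_sequence`.
#' @export
read_frame_sequence <- function(directory,
                                manifest_path = file.path(directory,
                                                          "manifest.csv")) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("filename", "time_s") %in% names(man))) {
    stop("manifest must have columns 'filename' and 'time_s'", call. = FALSE)
  }
  times <- suppressWarnings(as.numeric(man$time_s))
  bad <- which(is.na(times))
  if (length(bad)) {
    stop(sprintf("unparseable timestamp for frame '%s'", man$filename[bad[1]]),
         call. = FALSE)
  }
  frames <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    path <- file.path(directory, man$filename[i])
    if (!file.exists(path)) {
      stop(sprintf("frame file missing: %s", man$filename[i]), call. = FALSE)
    }
    img <- tryCatch(read_image(path), error = function(e) {
      stop(sprintf("cannot read frame '%s': %s", man$filename[i],
                   conditionMessage(e)), call. = FALSE)
    })
    frames[[i]] <- frame_record(times[i], img)
  }
  dims <- vapply(frames, function(f) dim(f$image)[1:2], numeric(2))
  off <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(off)) {
    stop(sprintf("frame '%s' has inconsistent dimensions (%d x %d, expected %d x %d)",
                 man$filename[off[1]], dims[1, off[1]], dims[2, off[1]],
                 dims[1, 1], dims[2, 1]), call. = FALSE)
  }
  frame_sequence(frames)
}
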