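# Chamber ROIs: circular pixel regions fixed by the chip geometry. Pixel
# coordinates are 0-based, row-major; a pixel belongs to an ROI when its
# center (its integer index) lies within `radius` of the ROI center.

#' Define one chamber region of interest
#'
#' @param chamber_id Character label for the reaction chamber.
#' @param center_row,center_col ROI center in 0-based pixel coordinates.
#' @param radius ROI radius in pixels (> 0).
#' @return A one-row data frame of class `chamber_roi`.
#' @export
chamber_roi <- function(chamber_id, center_row, center_col, radius) {
  if (!is.numeric(radius) || radius <= 0) {
    stop("radius must be > 0", call. = FALSE)
  }
  structure(
    data.frame(chamber_id = as.character(chamber_id),
               center_row = as.numeric(center_row),
               center_col = as.numeric(center_col),
               radius = as.numeric(radius),
               stringsAsFactors = FALSE),
    class = c("chamber_roi", "data.frame")
  )
}

#' Bind chamber ROIs into a validated set
#'
#' Checks that chamber ids are unique and that the circular regions are
#' pairwise disjoint (center distance greater than the radius sum).
#'
#' @param ... `chamber_roi` rows or data frames with the same columns.
#' @return A data frame of class `roi_set`.
#' @export
roi_set <- function(...) {
  rois <- do.call(rbind, lapply(list(...), as.data.frame))
  needed <- c("chamber_id", "center_row", "center_col", "radius")
  if (!all(needed %in% names(rois))) {
    stop("ROIs need columns chamber_id, center_row, center_col, radius",
         call. = FALSE)
  }
  if (anyDuplicated(rois$chamber_id)) {
    stop("chamber_id values must be unique", call. = FALSE)
  }
  n <- nrow(rois)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- sqrt((rois$center_row[i] - rois$center_row[j])^2 +
                  (rois$center_col[i] - rois$center_col[j])^2)
        if (d <= rois$radius[i] + rois$radius[j]) {
          stop(sprintf("ROIs '%s' and '%s' overlap", rois$chamber_id[i],
                       rois$chamber_id[j]), call. = FALSE)
        }
      }
    }
  }
  structure(rois, class = c("roi_set", "data.frame"))
}

#' Read a chamber-ROI geometry config
#'
#' Accepts YAML or JSON: a list of records with fields `chamber_id`,
#' `center_row`, `center_col`, `radius` (0-based pixel coordinates).
#'
#' @param path Path to the `.yaml`/`.yml` or `.json` config.
#' @return A validated `roi_set`.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("ROI config not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop(sprintf("unsupported ROI config format '%s'", ext), call. = FALSE)
  }
  rows <- lapply(raw, function(r) {
    chamber_roi(r$chamber_id, r$center_row, r$center_col, r$radius)
  })
  do.call(roi_set, rows)
}

#' Write a chamber-ROI geometry config (YAML)
#'
#' @param rois An `roi_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  recs <- lapply(seq_len(nrow(rois)), function(i) {
    list(chamber_id = rois$chamber_id[i],
         center_row = rois$center_row[i],
         center_col = rois$center_col[i],
         radius = rois$radius[i])
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

# 0-based (row, col) index matrix of pixels inside one circular ROI,
# restricted to an H x W frame after validating containment.
.roi_pixels <- function(roi, frame_dim) {
  h <- frame_dim[1]; w <- frame_dim[2]
  cr <- roi$center_row; cc <- roi$center_col; r <- roi$radius
  if (cr - r < 0 || cr + r > h - 1 || cc - r < 0 || cc + r > w - 1) {
    stop(sprintf("ROI '%s' extends outside the %d x %d frame",
                 roi$chamber_id, h, w), call. = FALSE)
  }
  rows <- seq.int(max(0, floor(cr - r)), min(h - 1, ceiling(cr + r)))
  cols <- seq.int(max(0, floor(cc - r)), min(w - 1, ceiling(cc + r)))
  grid <- expand.grid(row = rows, col = cols)
  keep <- (grid$row - cr)^2 + (grid$col - cc)^2 <= r^2
  as.matrix(grid[keep, , drop = FALSE])
}

#' Mean RGB over a circular chamber ROI
#'
#' Arithmetic mean, per channel, of the pixels whose centers fall within the
#' ROI radius; values on the \[0, 1\] scale.
#'
#' @param frame A [frame_record()].
#' @param roi A `chamber_roi` (one row).
#' @return Named numeric vector `c(r, g, b)`.
#' @export
roi_mean <- function(frame, roi) {
  px <- .roi_pixels(roi, dim(frame$image)[1:2])
  idx1 <- cbind(px[, "row"] + 1L, px[, "col"] + 1L)
  c(r = mean(frame$image[, , 1L][idx1]),
    g = mean(frame$image[, , 2L][idx1]),
    b = mean(frame$image[, , 3L][idx1]))
}
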