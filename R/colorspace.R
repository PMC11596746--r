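# CIE color-space conversions used to turn per-chamber RGB means into
# L*a*b*/hue signals. The conversion is applied to raw 8-bit pixel values
# scaled to [0, 1]; no sRGB gamma decoding is performed by default, matching
# the instrument's analysis chain (see the methods vignette). The XYZ matrix
# rows sum exactly to the white point (Xn, Yn, Zn), so gray inputs map to
# a* = b* = 0.

# sRGB-primaries RGB -> XYZ matrix (D65-like white point).
.XYZ_MATRIX <- matrix(c(
  0.4124, 0.3576, 0.1805,
  0.2126, 0.7152, 0.0722,
  0.0193, 0.1192, 0.9505
), nrow = 3L, byrow = TRUE)

.WHITE_POINT <- c(Xn = 0.9505, Yn = 1.0, Zn = 1.089)

# CIE threshold (24/116)^3 ~= 0.008856 and linear slope 841/108.
.LAB_EPS <- (24 / 116)^3

#' Convert RGB to CIE XYZ tristimulus values
#'
#' Applies the linear 3x3 sRGB-primaries matrix directly to pixel values
#' scaled to \[0, 1\] (8-bit value / 255). No gamma decoding is applied by
#' default: the instrument's JPEG pixel values are used as-is. Set
#' `gamma_decode = TRUE` to linearize with the standard sRGB transfer
#' function first.
#'
#' @param rgb Numeric vector of length 3 (R, G, B) or an n x 3 matrix, all
#'   components in \[0, 1\].
#' @param gamma_decode Logical; decode sRGB gamma before the matrix product.
#' @return A matrix with columns `X`, `Y`, `Z` (a 1 x 3 matrix for vector
#'   input). The white point (1, 1, 1) maps to (0.9505, 1.0, 1.089).
#' @examples
#' rgb_to_xyz(c(1, 1, 1))   # white point
#' rgb_to_xyz(c(1, 0, 0))   # first matrix column
#' @seealso [xyz_to_lab()], [hue_angle()]
#' @export
rgb_to_xyz <- function(rgb, gamma_decode = FALSE) {
  rgb <- .as_triple_matrix(rgb, "rgb")
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 1)) {
    stop("rgb components must be finite and in [0, 1]", call. = FALSE)
  }
  if (gamma_decode) {
    rgb <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  }
  xyz <- rgb %*% t(.XYZ_MATRIX)
  colnames(xyz) <- c("X", "Y", "Z")
  xyz
}

#' Convert CIE XYZ to CIELAB (with hue angle)
#'
#' Uses the white point Xn = 0.9505, Yn = 1.0, Zn = 1.089 and the standard
#' CIE piecewise companding function: cube root above (24/116)^3, the linear
#' branch (841/108) x + 16/116 below. The hue angle column `h` is the
#' four-quadrant arctangent of (b*, a*) in degrees in \[0, 360), and is `NA`
#' for achromatic colors (a* = b* = 0).
#'
#' @param xyz Numeric vector of length 3 (X, Y, Z) or an n x 3 matrix, all
#'   components >= 0.
#' @return A matrix with columns `L`, `a`, `b`, `h`.
#' @examples
#' xyz_to_lab(c(0.9505, 1, 1.089))  # L = 100, a = b = 0
#' xyz_to_lab(rgb_to_xyz(c(0.2, 0.4, 0.8)))
#' @export
xyz_to_lab <- function(xyz) {
  xyz <- .as_triple_matrix(xyz, "xyz")
  if (anyNA(xyz) || any(xyz < 0)) {
    stop("xyz components must be finite and >= 0", call. = FALSE)
  }
  fx <- .lab_f(xyz[, 1L] / .WHITE_POINT[["Xn"]])
  fy <- .lab_f(xyz[, 2L] / .WHITE_POINT[["Yn"]])
  fz <- .lab_f(xyz[, 3L] / .WHITE_POINT[["Zn"]])
  L <- 116 * fy - 16
  a <- 500 * (fx - fy)
  b <- 200 * (fy - fz)
  h <- rep(NA_real_, length(L))
  chromatic <- a != 0 | b != 0
  if (any(chromatic)) {
    h[chromatic] <- hue_angle(a[chromatic], b[chromatic])
  }
  cbind(L = L, a = a, b = b, h = h)
}

#' Hue angle from CIELAB opponent axes
#'
#' Four-quadrant arctangent of (b*, a*), mapped to degrees in \[0, 360).
#' The achromatic point a* = b* = 0 has no hue and is an error.
#'
#' @param a,b Numeric vectors of a* and b* values (recycled to a common
#'   length).
#' @return Hue angle(s) in degrees in \[0, 360).
#' @examples
#' hue_angle(0, 1)    # 90
#' hue_angle(1, 1)    # 45
#' hue_angle(-1, 0)   # 180
#' @export
hue_angle <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  if (anyNA(a) || anyNA(b)) stop("a and b must be finite", call. = FALSE)
  if (any(a == 0 & b == 0)) {
    stop("hue is undefined for the achromatic point a = b = 0", call. = FALSE)
  }
  (atan2(b, a) * 180 / pi) %% 360
}

.lab_f <- function(x) {
  ifelse(x > .LAB_EPS, x^(1 / 3), (841 / 108) * x + 16 / 116)
}

.as_triple_matrix <- function(x, what) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) {
      stop(sprintf("%s must have 3 components", what), call. = FALSE)
    }
    x <- matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) {
      stop(sprintf("%s must have 3 columns", what), call. = FALSE)
    }
    storage.mode(x) <- "double"
  }
  x
}
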