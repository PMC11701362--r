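# Colour-space conversions and the CIE76 delta-E contrast metric.
#
# All converters accept either a length-3 numeric vector (one colour) or an
# n x 3 matrix (one colour per row) and return the matching shape. Channels
# are real-valued: ROI means are carried at full precision, never
# re-quantised to 8 bits.

# sRGB (linear) -> CIE XYZ, D65 / 2 degree observer, IEC 61966-2-1 primaries.
.srgb_xyz_matrix <- matrix(c(
  0.41239079926595934, 0.35758433938387796, 0.18048078840183429,
  0.21263900587151027, 0.71516867876775593, 0.07219231536073371,
  0.01933081871559182, 0.11919477979462598, 0.95053215224966058),
  nrow = 3, byrow = TRUE)

# Reference white = image of RGB (255,255,255); guarantees white -> (100,0,0).
.ref_white <- rowSums(.srgb_xyz_matrix)

.as_rgb_matrix <- function(x, arg = "x") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) {
      stop(sprintf("'%s' must be a length-3 RGB vector or an n x 3 matrix", arg),
           call. = FALSE)
    }
    x <- matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) {
      stop(sprintf("'%s' must have 3 columns (R, G, B)", arg), call. = FALSE)
    }
    storage.mode(x) <- "double"
  }
  if (anyNA(x)) stop("RGB values must not contain NA", call. = FALSE)
  if (any(x < 0 | x > 255)) {
    stop("RGB channel values must lie in [0, 255]", call. = FALSE)
  }
  x
}

.drop_if_vector <- function(res, x) {
  if (is.null(dim(x))) res[1L, ] else res
}

#' Convert sRGB colours to CIE-L*a*b*
#'
#' Decodes 8-bit sRGB (IEC 61966-2-1 transfer function), converts to CIE XYZ
#' under D65 / 2 degree observer, then to CIE 1976 L*a*b*. The reference
#' white is the XYZ image of RGB white, so (255,255,255) maps to exactly
#' (100, 0, 0) and the whole grey ramp has a* = b* = 0 up to quantisation.
#'
#' @param x Length-3 numeric vector `c(r, g, b)` or an n x 3 matrix, channel
#'   values in `[0, 255]`. Real-valued channels (e.g. ROI means) are allowed.
#' @return Same shape as the input with columns/elements `L`, `a`, `b`.
#'   `L` lies in `[0, 100]` for any valid input.
#' @examples
#' srgb_to_lab(c(255, 255, 255))   # L* = 100, a* = b* = 0
#' srgb_to_lab(c(255, 0, 0))       # saturated red
#' @export
srgb_to_lab <- function(x) {
  rgb <- .as_rgb_matrix(x)
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_xyz_matrix)
  tt <- sweep(xyz, 2L, .ref_white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(tt > eps, tt^(1 / 3), tt / (3 * (6 / 29)^2) + 4 / 29)
  out <- cbind(L = 116 * f[, 2L] - 16,
               a = 500 * (f[, 1L] - f[, 2L]),
               b = 200 * (f[, 2L] - f[, 3L]))
  .drop_if_vector(out, x)
}

#' Convert sRGB colours to HSV
#'
#' Standard hexcone model: hue in degrees `[0, 360)`, saturation and value as
#' fractions in `[0, 1]`.
#'
#' @inheritParams srgb_to_lab
#' @return Same shape as the input with columns/elements `H`, `S`, `V`.
#' @examples
#' srgb_to_hsv(c(255, 0, 0))     # H = 0, S = 1, V = 1
#' srgb_to_hsv(c(128, 128, 128)) # grey: S = 0
#' @export
srgb_to_hsv <- function(x) {
  rgb <- .as_rgb_matrix(x)
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 255))
  out <- cbind(H = (hsv[, 1L] * 360) %% 360, S = hsv[, 2L], V = hsv[, 3L])
  .drop_if_vector(out, x)
}

#' CIE76 colour difference (delta-E)
#'
#' Euclidean distance between two points in CIE-L*a*b*:
#' \eqn{\Delta E = \sqrt{\Delta L^{*2} + \Delta a^{*2} + \Delta b^{*2}}}.
#' This is the contrast metric used throughout: a colour-agnostic magnitude
#' of colour change between a frame and the reference frame.
#'
#' @param x,y Length-3 `c(L, a, b)` vectors or n x 3 matrices (recycled
#'   row-wise if one side is a single colour).
#' @return Non-negative numeric vector of distances.
#' @examples
#' delta_e(c(100, 0, 0), c(0, 0, 0))  # 100
#' @export
delta_e <- function(x, y) {
  xm <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  ym <- if (is.null(dim(y))) matrix(as.numeric(y), nrow = 1L) else as.matrix(y)
  if (ncol(xm) != 3L || ncol(ym) != 3L) {
    stop("Lab colours must have 3 components (L, a, b)", call. = FALSE)
  }
  n <- max(nrow(xm), nrow(ym))
  if (nrow(xm) == 1L) xm <- xm[rep(1L, n), , drop = FALSE]
  if (nrow(ym) == 1L) ym <- ym[rep(1L, n), , drop = FALSE]
  if (nrow(xm) != nrow(ym)) {
    stop("'x' and 'y' must have the same number of colours", call. = FALSE)
  }
  d <- xm - ym
  unname(sqrt(rowSums(d * d)))
}

#' Mean colour of a pixel collection
#'
#' Arithmetic per-channel mean in sRGB. Averaging happens in RGB *before* any
#' colour-space conversion (the default throughout the pipeline); the result
#' keeps real-valued channels.
#'
#' @param pixels n x 3 matrix of RGB rows, channel values in `[0, 255]`.
#' @return Length-3 named numeric vector `c(R, G, B)`.
#' @export
mean_colour <- function(pixels) {
  px <- .as_rgb_matrix(pixels, "pixels")
  if (nrow(px) == 0L) stop("'pixels' must contain at least one pixel", call. = FALSE)
  stats::setNames(colMeans(px), c("R", "G", "B"))
}
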