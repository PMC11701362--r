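# Independent oracles used to pin expected values. Each is deliberately
# written along a different code path from the package implementation.

# CIE-formula oracle: scalar, per-channel, with the sRGB -> XYZ matrix
# derived on the spot from the published primary and D65 white
# chromaticities (not copied from the implementation's constants).
oracle_srgb_to_lab <- function(rgb) {
  prim <- matrix(c(0.64, 0.33, 0.30, 0.60, 0.15, 0.06), 2)
  w <- c(0.3127, 0.3290)
  Xc <- rbind(prim[1, ] / prim[2, ], 1, (1 - colSums(prim)) / prim[2, ])
  S <- solve(Xc, c(w[1] / w[2], 1, (1 - sum(w)) / w[2]))
  M <- Xc %*% diag(S)
  white <- as.vector(M %*% c(1, 1, 1))
  lin <- numeric(3)
  for (ch in 1:3) {
    v <- rgb[ch] / 255
    lin[ch] <- if (v <= 0.04045) v / 12.92 else ((v + 0.055) / 1.055)^2.4
  }
  xyz <- as.vector(M %*% lin)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(xyz[1] / white[1]); fy <- f(xyz[2] / white[2]); fz <- f(xyz[3] / white[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Brute-force disk membership: test every pixel of the frame against the
# inclusive <= radius rule.
oracle_disk_pixels <- function(cx, cy, radius, frame_height, frame_width) {
  out <- NULL
  for (row in 0:(frame_height - 1)) {
    for (col in 0:(frame_width - 1)) {
      if ((row - cy)^2 + (col - cx)^2 <= radius^2 + 1e-9) {
        out <- rbind(out, c(row = row, col = col))
      }
    }
  }
  out
}

# Closed-form ordinary least squares.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Direct plug-in MI over an explicitly built joint histogram, double loop.
oracle_mi <- function(x, y, bins) {
  n <- length(x)
  bx <- ceiling(bins * rank(x, ties.method = "first") / n)
  by <- ceiling(bins * rank(y, ties.method = "first") / n)
  mi <- 0
  for (i in seq_len(bins)) {
    for (j in seq_len(bins)) {
      pij <- sum(bx == i & by == j) / n
      if (pij > 0) {
        mi <- mi + pij * log(pij / ((sum(bx == i) / n) * (sum(by == j) / n)))
      }
    }
  }
  max(mi, 0)
}

# Uniform single-colour frame.
make_frame <- function(h, w, colour) {
  array(rep(colour, each = h * w), dim = c(h, w, 3))
}

# A small single-well mask centred in an h x w frame.
centre_mask <- function(h, w, diameter = min(h, w) - 3) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  build_masks(grid_spec(1, 1, c(floor(cx), floor(cy)), 1, diameter), h, w)[[1]]
}

# Small standard two-well test plate used across kinetics tests.
demo_plate <- function(wells, fps = 5, duration = 300, noise_sd = 0,
                       seed = 1L, diameter = 12) {
  grid <- grid_spec(1, length(wells), origin = c(10, 10),
                    pitch = diameter + 6, diameter = diameter)
  names(wells) <- grid_labels(grid)
  plate_video_spec(grid, wells, 10 + diameter + 3,
                   10 + (length(wells) - 1) * (diameter + 6) + diameter + 3,
                   fps = fps, duration = duration, noise_sd = noise_sd,
                   seed = seed)
}
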