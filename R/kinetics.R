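# Per-ROI colour kinetics: trace extraction, delta-E profiles, plateau
# end-point detection, induction times, and area under the curve.

#' Extract per-ROI colour traces from a frame sequence
#'
#' For every mask and frame the region's mean sRGB colour is computed over
#' the mask's pixel set, converted to CIE-L*a*b* and HSV, and the CIE76
#' delta-E against the *same region's* colour in the reference frame is
#' recorded. Each well is therefore compared with its own starting colour.
#'
#' @param fs A [frame_seq()] or a streaming `frame_source` (see
#'   [plate_frame_source()]).
#' @param masks An `roi_masks` object from [build_masks()] matching the frame
#'   dimensions.
#' @param reference_index 1-based index of the reference frame (default: the
#'   first frame, so `deltaE[1] == 0`).
#' @param average `"rgb"` (default) averages pixels in sRGB and converts the
#'   mean; `"lab"` converts each pixel first and averages L*, a*, b* (delta-E
#'   then uses the Lab mean; HSV is still derived from the RGB mean).
#' @return A `colour_traces` tibble in long format: one row per (ROI, frame)
#'   with columns `label, time_s, R, G, B, L, a, b, H, S, V, deltaE`.
#' @export
extract_traces <- function(fs, masks, reference_index = 1L,
                           average = c("rgb", "lab")) {
  average <- match.arg(average)
  if (!inherits(masks, "roi_masks")) stop("'masks' must come from build_masks()", call. = FALSE)
  src <- .as_frame_source(fs)
  H <- attr(masks, "frame_height"); W <- attr(masks, "frame_width")
  if (src$height != H || src$width != W) {
    stop(sprintf("masks were built for a %d x %d frame but frames are %d x %d",
                 H, W, src$height, src$width), call. = FALSE)
  }
  n <- src$n_frames
  if (reference_index < 1L || reference_index > n) {
    stop("'reference_index' out of range", call. = FALSE)
  }
  m <- length(masks)
  plane <- as.integer(H) * as.integer(W)
  rgb <- lapply(seq_len(m), function(i) matrix(NA_real_, n, 3L))
  lab_px <- if (average == "lab") lapply(seq_len(m), function(i) matrix(NA_real_, n, 3L))
  for (k in seq_len(n)) {
    fr <- src$get_frame(k)
    fv <- as.vector(fr)
    for (i in seq_len(m)) {
      idx <- masks[[i]]$idx
      px <- cbind(fv[idx], fv[idx + plane], fv[idx + 2L * plane])
      rgb[[i]][k, ] <- colMeans(px)
      if (average == "lab") lab_px[[i]][k, ] <- colMeans(srgb_to_lab(px))
    }
  }
  out <- vector("list", m)
  for (i in seq_len(m)) {
    lab <- if (average == "lab") lab_px[[i]] else srgb_to_lab(rgb[[i]])
    hsv <- srgb_to_hsv(rgb[[i]])
    de <- delta_e(lab, lab[reference_index, , drop = FALSE])
    out[[i]] <- tibble::tibble(
      label = masks[[i]]$label, time_s = src$times,
      R = rgb[[i]][, 1L], G = rgb[[i]][, 2L], B = rgb[[i]][, 3L],
      L = lab[, 1L], a = lab[, 2L], b = lab[, 3L],
      H = hsv[, 1L], S = hsv[, 2L], V = hsv[, 3L],
      deltaE = de)
  }
  res <- do.call(rbind, out)
  class(res) <- c("colour_traces", class(res))
  res
}

.as_frame_source <- function(fs) {
  if (inherits(fs, "frame_source")) return(fs)
  if (inherits(fs, "frame_seq")) {
    return(structure(list(n_frames = fs$n_frames, fps = fs$fps,
                          times = fs$times, height = fs$height,
                          width = fs$width,
                          get_frame = function(i) fs$frames[[i]]),
                     class = "frame_source"))
  }
  stop("'fs' must be a frame_seq or frame_source", call. = FALSE)
}

#' Split a traces table by ROI label
#'
#' @param traces A `colour_traces` tibble.
#' @return Named list of single-ROI tibbles, in order of first appearance.
#' @export
split_traces <- function(traces) {
  split(as.data.frame(traces), factor(traces$label, levels = unique(traces$label)))
}

#' Centred moving average with shrinking edges
#'
#' Smooths a series with an odd, centred window; near the edges the window
#' shrinks to what fits, so the output has the input's length and a linear
#' ramp is unchanged in the interior.
#'
#' @param x Numeric series.
#' @param window Odd positive integer, `<= length(x)`.
#' @return Smoothed series, same length as `x`.
#' @export
smooth_series <- function(x, window) {
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("'window' must be odd and >= 1", call. = FALSE)
  if (window > n) stop("'window' must not exceed the series length", call. = FALSE)
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Time derivative of a sampled series
#'
#' Central differences in the interior, one-sided at the ends. With a
#' delta-E series the result is in delta-E per second.
#'
#' @param y Numeric series (length >= 2).
#' @param t Sampling times, strictly increasing, same length as `y`.
#' @return Derivative series, same length as `y`.
#' @export
series_gradient <- function(y, t) {
  n <- length(y)
  if (n < 2L) stop("need at least 2 samples to differentiate", call. = FALSE)
  if (length(t) != n) stop("'y' and 't' lengths differ", call. = FALSE)
  g <- numeric(n)
  g[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  g[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    g[i] <- (y[i + 1L] - y[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  g
}

#' End-point detection parameters
#'
#' @param gradient_threshold Plateau threshold on d(deltaE)/dt in
#'   delta-E per second (default 0.05).
#' @param smoothing_window Odd number of frames for the centred moving
#'   average applied before differentiation (default 25, i.e. 1 s at
#'   25 fps).
#' @param persistence_s Seconds the gradient must stay below the threshold
#'   for the crossing to count as a plateau (default 10).
#' @return An `endpoint_config` object.
#' @export
endpoint_config <- function(gradient_threshold = 0.05, smoothing_window = 25L,
                            persistence_s = 10) {
  if (gradient_threshold <= 0) stop("'gradient_threshold' must be > 0", call. = FALSE)
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L) {
    stop("'smoothing_window' must be odd and >= 1", call. = FALSE)
  }
  if (persistence_s < 0) stop("'persistence_s' must be >= 0", call. = FALSE)
  structure(list(gradient_threshold = gradient_threshold,
                 smoothing_window = smoothing_window,
                 persistence_s = persistence_s),
            class = "endpoint_config")
}

.smoothed_gradient <- function(time_s, series, config) {
  series_gradient(smooth_series(series, config$smoothing_window), time_s)
}

#' Detect a reaction end point by plateau analysis
#'
#' The delta-E profile is smoothed, differentiated, and scanned for the
#' plateau that follows the colour change: the reaction must first *activate*
#' (gradient reaches the threshold at some time), and the end point is the
#' earliest later time at which the gradient falls below the threshold and
#' stays below it for the persistence duration. Without the activation rule
#' the flat pre-reaction baseline would trigger at t = 0; without
#' persistence a brief stall would. `NA` means no plateau was detected
#' (reaction incomplete or never started).
#'
#' @param time_s Sampling times (seconds, uniform).
#' @param delta_e delta-E series, same length.
#' @param config An [endpoint_config()].
#' @return End-point time in seconds, or `NA_real_`.
#' @export
detect_endpoint <- function(time_s, delta_e, config = endpoint_config()) {
  n <- length(delta_e)
  if (n < config$smoothing_window) {
    stop("trace shorter than the smoothing window", call. = FALSE)
  }
  g <- .smoothed_gradient(time_s, delta_e, config)
  thr <- config$gradient_threshold
  act <- which(g >= thr)
  if (length(act) == 0L) return(NA_real_)
  a0 <- act[1L]
  below <- g < thr
  below[seq_len(a0)] <- FALSE
  i <- a0 + 1L
  while (i <= n) {
    if (below[i]) {
      run_end <- i
      while (run_end < n && below[run_end + 1L]) run_end <- run_end + 1L
      if (time_s[run_end] - time_s[i] >= config$persistence_s) return(time_s[i])
      i <- run_end + 1L
    } else {
      i <- i + 1L
    }
  }
  NA_real_
}

#' Induction time of a colour channel
#'
#' The induction period ends when the rate of colour change peaks: the
#' default estimate is the time of the maximum absolute smoothed gradient of
#' the chosen channel (for sigmoidal profiles this is the inflection point,
#' e.g. the reddening a* midpoint in sugar-mediated reductions). A
#' threshold-crossing variant returns the first time the absolute gradient
#' reaches `threshold` instead.
#'
#' @param time_s Sampling times (seconds).
#' @param series Channel values (e.g. the `a` column of a trace).
#' @param config An [endpoint_config()] (only the smoothing window is used).
#' @param mode `"max_rate"` (default) or `"threshold"`.
#' @param threshold Gradient threshold (channel units per second) for
#'   `mode = "threshold"`.
#' @return Induction time in seconds, or `NA_real_` for a constant series
#'   (or when the threshold is never reached).
#' @export
induction_time <- function(time_s, series, config = endpoint_config(),
                           mode = c("max_rate", "threshold"), threshold = NULL) {
  mode <- match.arg(mode)
  if (length(series) < config$smoothing_window) {
    stop("trace shorter than the smoothing window", call. = FALSE)
  }
  if (diff(range(series)) < 1e-12) return(NA_real_)
  g <- abs(.smoothed_gradient(time_s, series, config))
  if (mode == "max_rate") return(time_s[which.max(g)])
  if (is.null(threshold) || threshold <= 0) {
    stop("'threshold' must be a positive number for mode = 'threshold'", call. = FALSE)
  }
  hit <- which(g >= threshold)
  if (length(hit) == 0L) NA_real_ else time_s[hit[1L]]
}

#' Area under the delta-E--time curve
#'
#' Trapezoidal integral over the full recorded span, in delta-E seconds.
#' Used for sedimentation grading: slower clearance of a turbid sample keeps
#' delta-E elevated longer and yields a larger area.
#'
#' @param time_s Sampling times (seconds, length >= 2).
#' @param delta_e delta-E series, same length.
#' @return Non-negative scalar.
#' @export
trace_auc <- function(time_s, delta_e) {
  if (length(time_s) < 2L) stop("need at least 2 frames for an integral", call. = FALSE)
  if (length(time_s) != length(delta_e)) stop("length mismatch", call. = FALSE)
  pracma::trapz(time_s, delta_e)
}

#' Kinetic summary of every ROI
#'
#' Applies [detect_endpoint()], [induction_time()], the maximum smoothed
#' delta-E rate, and [trace_auc()] to each ROI's trace.
#'
#' @param traces A `colour_traces` tibble from [extract_traces()].
#' @param config An [endpoint_config()].
#' @param induction_channel Channel for the induction time, one of
#'   `deltaE, L, a, b, H, S, V, R, G, B`.
#' @return Tibble with one row per ROI: `label, endpoint_s, induction_s,
#'   max_rate, auc, complete` (`complete` is `TRUE` when an end point was
#'   found; `NA` fields mean "no plateau detected / reaction incomplete").
#' @export
summarise_kinetics <- function(traces, config = endpoint_config(),
                               induction_channel = "deltaE") {
  if (!induction_channel %in% c("deltaE", "L", "a", "b", "H", "S", "V", "R", "G", "B")) {
    stop(sprintf("unknown channel '%s'", induction_channel), call. = FALSE)
  }
  per <- split_traces(traces)
  rows <- lapply(per, function(tr) {
    ep <- detect_endpoint(tr$time_s, tr$deltaE, config)
    ind <- induction_time(tr$time_s, tr[[induction_channel]], config)
    g <- abs(.smoothed_gradient(tr$time_s, tr$deltaE, config))
    tibble::tibble(label = tr$label[1L], endpoint_s = ep, induction_s = ind,
                   max_rate = max(g), auc = trace_auc(tr$time_s, tr$deltaE),
                   complete = !is.na(ep))
  })
  do.call(rbind, rows)
}

#' Write a kinetic summary to CSV
#'
#' `NA` end points / induction times (no plateau detected) are written as
#' empty fields.
#'
#' @param summary Tibble from [summarise_kinetics()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(summary, path) {
  readr::write_csv(summary, path, na = "")
  invisible(path)
}
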