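# Synthetic plate videos with programmed per-well colour kinetics.
#
# Every well's colour follows c(t) = colour_end + (colour_start -
# colour_end) * m(t), where m(t) is a monotone mixing function chosen per
# model. Linear interpolation happens in RGB; the curved L*a*b* trajectory
# seen in real dye-decay videos emerges from the sRGB -> Lab nonlinearity.
# A seed fixes all randomness, per frame, so streaming and in-memory
# rendering are bit-identical.

.well_models <- c("constant", "exponential_decay", "logistic", "step",
                  "turbidity_clear")

#' Programmed kinetics of one synthetic well
#'
#' Models: `constant` (no change); `exponential_decay` (first-order dye
#' decay, e.g. crystal violet decolourisation, rate `rate` after an optional
#' `lag`); `logistic` (sigmoidal change with `midpoint` and `steepness`);
#' `step` (instantaneous change at `step_time`); `turbidity_clear`
#' (exponential clearance scaled by `amplitude`, emulating a settling turbid
#' suspension whose initial cloudiness grows with suspended solid).
#'
#' @param model One of `"constant"`, `"exponential_decay"`, `"logistic"`,
#'   `"step"`, `"turbidity_clear"`.
#' @param colour_start,colour_end RGB triples (`c(r, g, b)` in `[0, 255]`).
#' @param rate First-order rate constant in 1/s (`exponential_decay`,
#'   `turbidity_clear`).
#' @param midpoint,steepness Logistic midpoint (s) and steepness (1/s).
#' @param lag Delay in seconds before the kinetics start (default 0).
#' @param step_time Step change time in seconds (`step`).
#' @param amplitude Fraction in `(0, 1]` of the start-to-end colour
#'   excursion realised at t = 0 (`turbidity_clear`).
#' @return A `well_kinetic_spec` object.
#' @export
well_kinetic_spec <- function(model, colour_start, colour_end = colour_start,
                              rate = NULL, midpoint = NULL, steepness = NULL,
                              lag = 0, step_time = NULL, amplitude = 1) {
  model <- match.arg(model, .well_models)
  colour_start <- as.numeric(.as_rgb_matrix(colour_start, "colour_start"))
  colour_end <- as.numeric(.as_rgb_matrix(colour_end, "colour_end"))
  if (lag < 0) stop("'lag' must be >= 0", call. = FALSE)
  need <- function(v, nm) {
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || v <= 0) {
      stop(sprintf("model '%s' needs positive '%s'", model, nm), call. = FALSE)
    }
  }
  if (model %in% c("exponential_decay", "turbidity_clear")) need(rate, "rate")
  if (model == "logistic") { need(midpoint, "midpoint"); need(steepness, "steepness") }
  if (model == "step") need(step_time, "step_time")
  if (model == "turbidity_clear" && (amplitude <= 0 || amplitude > 1)) {
    stop("'amplitude' must be in (0, 1]", call. = FALSE)
  }
  structure(list(model = model, colour_start = colour_start,
                 colour_end = colour_end, rate = rate, midpoint = midpoint,
                 steepness = steepness, lag = lag, step_time = step_time,
                 amplitude = amplitude),
            class = "well_kinetic_spec")
}

#' Mixing function m(t) of a well model
#'
#' `m = 1` reproduces `colour_start`, `m = 0` reproduces `colour_end`.
#'
#' @param well A [well_kinetic_spec()].
#' @param t Times in seconds (vectorised).
#' @return Numeric vector in `[0, 1]`.
#' @export
mixing_value <- function(well, t) {
  switch(well$model,
    constant = rep(1, length(t)),
    exponential_decay = exp(-well$rate * pmax(0, t - well$lag)),
    logistic = 1 / (1 + exp(well$steepness * (t - well$midpoint))),
    step = as.numeric(t < well$step_time),
    turbidity_clear = well$amplitude * exp(-well$rate * pmax(0, t - well$lag)))
}

#' Noise-free well colour at given times
#'
#' @param well A [well_kinetic_spec()].
#' @param t Times in seconds.
#' @return `length(t)` x 3 matrix of real-valued RGB rows.
#' @export
well_colour <- function(well, t) {
  m <- mixing_value(well, t)
  res <- outer(m, well$colour_start - well$colour_end)
  sweep(res, 2L, well$colour_end, "+")
}

#' Full specification of a synthetic plate video
#'
#' @param grid A [grid_spec()] placing the wells.
#' @param wells Named list of [well_kinetic_spec()]s keyed by grid label;
#'   every label in the grid must be covered.
#' @param frame_height,frame_width Frame dimensions in pixels.
#' @param fps Frames per second (default 25).
#' @param duration Recording length in seconds; frames at
#'   `0, 1/fps, ..., duration`.
#' @param noise_sd Per-pixel, per-channel Gaussian noise sigma in 8-bit
#'   counts (default 0).
#' @param background Background RGB (default mid grey `c(200, 200, 200)`).
#' @param glare Optional static saturated patch:
#'   `list(centre = c(x, y), radius, colour = c(255, 255, 255))`.
#' @param seed Integer fixing all randomness.
#' @return A `plate_video_spec` object (masks are realised and validated:
#'   out-of-frame or overlapping wells are an error).
#' @export
plate_video_spec <- function(grid, wells, frame_height, frame_width,
                             fps = 25, duration, noise_sd = 0,
                             background = c(200, 200, 200), glare = NULL,
                             seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  labels <- grid_labels(grid)
  if (!all(labels %in% names(wells))) {
    stop(sprintf("missing kinetic specs for wells: %s",
                 paste(setdiff(labels, names(wells)), collapse = ", ")), call. = FALSE)
  }
  ok <- vapply(wells[labels], inherits, logical(1L), "well_kinetic_spec")
  if (!all(ok)) stop("every well entry must be a well_kinetic_spec", call. = FALSE)
  if (duration <= 0 || fps <= 0) stop("'fps' and 'duration' must be positive", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  masks <- build_masks(grid, frame_height, frame_width)   # errors if out of frame
  ov <- masks_overlap(masks)
  if (ov$overlap) {
    stop(sprintf("well disks overlap (%s/%s, ...)", ov$pairs$a[1L], ov$pairs$b[1L]),
         call. = FALSE)
  }
  if (!is.null(glare)) {
    if (is.null(glare$colour)) glare$colour <- c(255, 255, 255)
    stopifnot(length(glare$centre) == 2L, glare$radius > 0)
  }
  structure(list(grid = grid, wells = wells[labels], masks = masks,
                 frame_height = as.integer(frame_height),
                 frame_width = as.integer(frame_width),
                 fps = fps, duration = duration, noise_sd = noise_sd,
                 background = as.numeric(background), glare = glare,
                 seed = as.integer(seed)),
            class = "plate_video_spec")
}

.glare_idx <- function(spec) {
  g <- spec$glare
  if (is.null(g)) return(integer(0))
  H <- spec$frame_height; W <- spec$frame_width
  gr <- expand.grid(row = 0:(H - 1L), col = 0:(W - 1L))
  keep <- (gr$row - g$centre[2L])^2 + (gr$col - g$centre[1L])^2 <= g$radius^2 + 1e-9
  gr$row[keep] + gr$col[keep] * H + 1L
}

#' Streaming frame source for a synthetic plate video
#'
#' Renders frames on demand so long recordings never need to sit in memory.
#' Noise is seeded per frame from the spec seed, so `get_frame(i)` is a pure
#' function and streaming matches [render_plate()] bit for bit.
#'
#' @param spec A [plate_video_spec()].
#' @param quantise Round channels to whole 8-bit counts (default `TRUE`);
#'   `FALSE` keeps real-valued channels, isolating time-discretisation
#'   effects from intensity quantisation in validation studies.
#' @return A `frame_source` (usable directly by [extract_traces()]).
#' @export
plate_frame_source <- function(spec, quantise = TRUE) {
  stopifnot(inherits(spec, "plate_video_spec"))
  n <- floor(spec$fps * spec$duration) + 1L
  times <- (seq_len(n) - 1L) / spec$fps
  H <- spec$frame_height; W <- spec$frame_width
  plane <- H * W
  gidx <- .glare_idx(spec)
  base <- array(rep(spec$background, each = plane), dim = c(H, W, 3L))
  masks <- spec$masks
  wells <- spec$wells
  get_frame <- function(i) {
    t <- times[i]
    fr <- base
    for (k in seq_along(masks)) {
      col <- well_colour(wells[[k]], t)
      idx <- masks[[k]]$idx
      fr[idx] <- col[1L]
      fr[idx + plane] <- col[2L]
      fr[idx + 2L * plane] <- col[3L]
    }
    if (length(gidx)) {     # specular glare sits on top of the sample colour
      for (ch in 1:3) fr[gidx + (ch - 1L) * plane] <- spec$glare$colour[ch]
    }
    if (spec$noise_sd > 0) {
      set.seed((spec$seed * 1009L + i) %% 2147483647L)
      fr <- fr + stats::rnorm(length(fr), sd = spec$noise_sd)
      fr[fr < 0] <- 0; fr[fr > 255] <- 255
    }
    if (quantise) fr <- round(fr)
    fr
  }
  structure(list(n_frames = n, fps = spec$fps, times = times,
                 height = H, width = W, get_frame = get_frame),
            class = "frame_source")
}

#' Render a synthetic plate video in memory
#'
#' @inheritParams plate_frame_source
#' @return A [frame_seq()] of all frames. For long recordings prefer
#'   [plate_frame_source()] and stream into [extract_traces()].
#' @export
render_plate <- function(spec, quantise = TRUE) {
  src <- plate_frame_source(spec, quantise = quantise)
  frame_seq(lapply(seq_len(src$n_frames), src$get_frame), fps = spec$fps)
}

#' Closed-form (noise-free) ground truth for a synthetic plate
#'
#' Evaluates each well's programmed colour trajectory on a dense time grid
#' (`dt` seconds, default 0.005), converts to L*a*b*, and derives the
#' continuous-curve delta-E profile against t = 0 and its derivative. The
#' reported end point is the earliest time after activation at which the
#' derivative falls below the threshold and stays there for the persistence
#' duration (same plateau rule as [detect_endpoint()], applied to the exact
#' curve, no smoothing); induction is the time of maximum absolute
#' derivative; AUC is the high-resolution trapezoidal integral (error
#' O(dt^2), far below one 8-bit quantisation step at the default `dt`).
#'
#' @param spec A [plate_video_spec()] (noise and quantisation ignored).
#' @param config An [endpoint_config()] (`smoothing_window` ignored).
#' @param dt Dense-grid resolution in seconds.
#' @return Tibble: `label, endpoint_s, induction_s, max_rate, auc`.
#' @export
analytic_summary <- function(spec, config = endpoint_config(), dt = 0.005) {
  stopifnot(inherits(spec, "plate_video_spec"))
  t <- seq(0, spec$duration, by = dt)
  rows <- lapply(seq_along(spec$wells), function(k) {
    well <- spec$wells[[k]]
    lab <- srgb_to_lab(well_colour(well, t))
    de <- delta_e(lab, lab[1L, , drop = FALSE])
    g <- series_gradient(de, t)
    thr <- config$gradient_threshold
    act <- which(g >= thr)
    ep <- NA_real_
    if (length(act)) {
      a0 <- act[1L]
      below <- g < thr
      below[seq_len(a0)] <- FALSE
      i <- a0 + 1L; n <- length(t)
      while (i <= n) {
        if (below[i]) {
          run_end <- i
          while (run_end < n && below[run_end + 1L]) run_end <- run_end + 1L
          if (t[run_end] - t[i] >= config$persistence_s) { ep <- t[i]; break }
          i <- run_end + 1L
        } else i <- i + 1L
      }
    }
    ind <- if (diff(range(de)) < 1e-12) NA_real_ else t[which.max(abs(g))]
    tibble::tibble(label = names(spec$wells)[k], endpoint_s = ep,
                   induction_s = ind, max_rate = max(abs(g)),
                   auc = pracma::trapz(t, de))
  })
  do.call(rbind, rows)
}

#' Write ground truth and rendering metadata as JSON
#'
#' @param spec A [plate_video_spec()].
#' @param summary Tibble from [analytic_summary()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(spec, summary, path) {
  meta <- list(
    fps = spec$fps, duration = spec$duration,
    frame_height = spec$frame_height, frame_width = spec$frame_width,
    noise_sd = spec$noise_sd, seed = spec$seed,
    wells = lapply(spec$wells, function(w) w[!vapply(w, is.null, logical(1L))]),
    ground_truth = summary)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
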