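# Grids of circular regions of interest (ROIs) and their pixel masks.
#
# Conventions (fixed so tests are bit-exact): pixel coordinates are 0-based
# (row, col) with the origin at the top-left; pixel centres sit at integer
# coordinates; a pixel belongs to an ROI iff its Euclidean distance to the
# ROI centre is <= radius (boundary inclusive).

#' Specify a grid of circular ROIs
#'
#' Describes a rows x columns grid of equally spaced circular regions, e.g.
#' the wells of a 24- or 96-well plate, by the centre of the first (top-left)
#' region, the centre-to-centre pitch, and a common diameter. Regions are
#' labelled row-letter + column-number (`A1`, `A2`, ..., row-major).
#'
#' @param n_rows,n_cols Positive integers; `n_rows` <= 26 (row letters A-Z).
#' @param origin Numeric `c(x, y)`: pixel coordinates of the first ROI centre
#'   (x = column direction, y = row direction, 0-based).
#' @param pitch Numeric `c(pitch_x, pitch_y)` centre spacing in pixels, or a
#'   single number used for both. Required positive whenever the grid has
#'   more than one column/row.
#' @param diameter ROI diameter in pixels (> 0).
#' @return A `grid_spec` object.
#' @examples
#' grid_spec(4, 6, origin = c(30, 30), pitch = 60, diameter = 40)
#' @export
grid_spec <- function(n_rows, n_cols, origin, pitch, diameter) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("'n_rows' and 'n_cols' must be positive integers", call. = FALSE)
  }
  if (n_rows > 26L) stop("grids with more than 26 rows are not supported", call. = FALSE)
  if (length(origin) != 2L || anyNA(origin)) {
    stop("'origin' must be c(x, y)", call. = FALSE)
  }
  if (length(pitch) == 1L) pitch <- c(pitch, pitch)
  if (length(pitch) != 2L || anyNA(pitch)) {
    stop("'pitch' must be one or two numbers", call. = FALSE)
  }
  if ((n_cols > 1L && pitch[1L] <= 0) || (n_rows > 1L && pitch[2L] <= 0)) {
    stop("'pitch' must be positive for multi-row/column grids", call. = FALSE)
  }
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0) {
    stop("'diameter' must be a positive number", call. = FALSE)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 origin = as.numeric(origin), pitch = as.numeric(pitch),
                 diameter = as.numeric(diameter)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("ROI grid: %d x %d, origin (%.1f, %.1f), pitch (%.1f, %.1f), diameter %.1f px\n",
              x$n_rows, x$n_cols, x$origin[1L], x$origin[2L],
              x$pitch[1L], x$pitch[2L], x$diameter))
  invisible(x)
}

#' Row-major labels of a grid
#'
#' @param grid A [grid_spec()].
#' @return Character vector `A1, A2, ..., B1, ...` of length
#'   `n_rows * n_cols`.
#' @export
grid_labels <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  as.vector(t(outer(LETTERS[seq_len(grid$n_rows)], seq_len(grid$n_cols), paste0)))
}

.grid_centres <- function(grid) {
  rows <- rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  cbind(x = grid$origin[1L] + cols * grid$pitch[1L],
        y = grid$origin[2L] + rows * grid$pitch[2L])
}

#' Realise an ROI grid as pixel masks
#'
#' Enumerates, for every region in the grid, the set of pixels whose centres
#' lie within `diameter / 2` of the region centre (inclusive). Masks are
#' returned in row-major order with their labels.
#'
#' @param grid A [grid_spec()].
#' @param frame_height,frame_width Frame dimensions in pixels.
#' @return An object of class `roi_masks`: a list of masks, each with
#'   `label`, `centre` (`c(x, y)`), `radius`, `pixels` (m x 2 integer matrix
#'   of 0-based `(row, col)` coordinates) and `idx` (1-based linear indices
#'   into an H x W matrix slice).
#' @examples
#' masks <- build_masks(grid_spec(1, 1, c(2, 2), 1, 2), 5, 5)
#' nrow(masks[[1]]$pixels)  # 5-pixel plus shape
#' @export
build_masks <- function(grid, frame_height, frame_width) {
  stopifnot(inherits(grid, "grid_spec"))
  frame_height <- as.integer(frame_height); frame_width <- as.integer(frame_width)
  if (frame_height < 1L || frame_width < 1L) {
    stop("frame dimensions must be positive", call. = FALSE)
  }
  centres <- .grid_centres(grid)
  labels <- grid_labels(grid)
  r <- grid$diameter / 2
  masks <- vector("list", nrow(centres))
  for (k in seq_len(nrow(centres))) {
    cx <- unname(centres[k, "x"]); cy <- unname(centres[k, "y"])
    if (cx - r < 0 || cx + r > frame_width - 1L ||
        cy - r < 0 || cy + r > frame_height - 1L) {
      stop(sprintf("ROI '%s' (centre %.1f, %.1f, radius %.1f) extends beyond the %d x %d frame",
                   labels[k], cx, cy, r, frame_height, frame_width), call. = FALSE)
    }
    rows <- seq.int(max(0L, floor(cy - r)), min(frame_height - 1L, ceiling(cy + r)))
    cols <- seq.int(max(0L, floor(cx - r)), min(frame_width - 1L, ceiling(cx + r)))
    gr <- expand.grid(row = rows, col = cols)
    keep <- (gr$row - cy)^2 + (gr$col - cx)^2 <= r^2 + 1e-9
    px <- as.matrix(gr[keep, , drop = FALSE])
    storage.mode(px) <- "integer"
    rownames(px) <- NULL
    masks[[k]] <- list(label = labels[k], centre = c(x = cx, y = cy), radius = r,
                       pixels = px,
                       idx = px[, "row"] + px[, "col"] * frame_height + 1L)
  }
  structure(masks, class = "roi_masks",
            frame_height = frame_height, frame_width = frame_width)
}

#' @export
print.roi_masks <- function(x, ...) {
  cat(sprintf("%d ROI masks in a %d x %d px frame (%s ... %s)\n",
              length(x), attr(x, "frame_height"), attr(x, "frame_width"),
              x[[1L]]$label, x[[length(x)]]$label))
  invisible(x)
}

#' Check an ROI mask set for overlapping regions
#'
#' QC guard: regions that share pixels yield contaminated colour means.
#'
#' @param masks An `roi_masks` object (or plain list of masks).
#' @return List with `overlap` (logical) and `pairs` (data frame of
#'   offending label pairs, zero rows when disjoint).
#' @export
masks_overlap <- function(masks) {
  if (length(masks) < 1L) stop("need at least one mask", call. = FALSE)
  keys <- lapply(masks, function(m) paste(m$pixels[, "row"], m$pixels[, "col"]))
  labels <- vapply(masks, `[[`, character(1L), "label")
  pairs <- list()
  if (length(masks) > 1L) {
    for (i in seq_len(length(masks) - 1L)) {
      for (j in seq.int(i + 1L, length(masks))) {
        if (any(keys[[i]] %in% keys[[j]])) {
          pairs[[length(pairs) + 1L]] <- data.frame(a = labels[i], b = labels[j])
        }
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a = character(0), b = character(0))
  list(overlap = nrow(pairs) > 0L, pairs = pairs)
}
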