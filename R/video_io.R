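# Frame acquisition and trace serialisation.
#
# Frames are H x W x 3 numeric arrays with channel values in [0, 255]
# (real-valued; file readers rescale from [0,1]). A frame sequence carries a
# uniform frame rate so that frame k (0-based) has timestamp k / fps.

#' Construct an in-memory frame sequence
#'
#' @param frames List of H x W x 3 numeric arrays, values in `[0, 255]`.
#' @param fps Frames per second (> 0); frame k (0-based) gets timestamp
#'   `k / fps`.
#' @return A `frame_seq` object with elements `frames`, `fps`, `times`.
#' @export
frame_seq <- function(frames, fps) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("'frames' must be a non-empty list of H x W x 3 arrays", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("'fps' must be a positive number", call. = FALSE)
  }
  d <- dim(frames[[1L]])
  if (length(d) != 3L || d[3L] != 3L) {
    stop("each frame must be an H x W x 3 array", call. = FALSE)
  }
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1L))
  if (!all(ok)) stop("all frames must share the same dimensions", call. = FALSE)
  structure(list(frames = frames, fps = as.numeric(fps),
                 times = (seq_along(frames) - 1L) / fps,
                 height = d[1L], width = d[2L], n_frames = length(frames)),
            class = "frame_seq")
}

#' @export
print.frame_seq <- function(x, ...) {
  cat(sprintf("frame_seq: %d frames, %d x %d px, %.6g fps (%.2f s)\n",
              x$n_frames, x$height, x$width, x$fps,
              (x$n_frames - 1L) / x$fps))
  invisible(x)
}

.read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' (PNG and TIFF are supported)", ext),
         call. = FALSE))
  if (length(dim(img)) == 2L) {                       # greyscale -> replicate
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3L] > 3L) {                     # drop alpha
    img <- img[, , 1:3, drop = FALSE]
  }
  img * 255
}

#' Read frames from an image sequence
#'
#' Reads a directory of numbered still images (PNG or TIFF, sorted by
#' zero-padded file name) into a [frame_seq()]. Image sequences carry no
#' intrinsic frame rate, so `fps` is required. Video containers (MP4/AVI)
#' must be expanded to an image sequence first (e.g.
#' `ffmpeg -i run.mp4 frames/frame_%06d.png`); pointing this reader at a
#' container file raises an error saying so.
#'
#' @param source Path to a directory of numbered images.
#' @param fps Frames per second of the original recording (required).
#' @return A [frame_seq()].
#' @export
read_frames <- function(source, fps = NULL) {
  if (!is.character(source) || length(source) != 1L) {
    stop("'source' must be a single path", call. = FALSE)
  }
  if (!file.exists(source)) stop(sprintf("'%s' does not exist", source), call. = FALSE)
  if (!dir.exists(source)) {
    ext <- tolower(tools::file_ext(source))
    if (ext %in% c("mp4", "avi", "mov", "mkv")) {
      stop(sprintf(paste0("'%s' is a video container; extract its frames to a ",
                          "numbered PNG sequence first (e.g. with ffmpeg) and ",
                          "pass that directory with the recording's fps"), source),
           call. = FALSE)
    }
    stop(sprintf("'%s' is not a directory of images", source), call. = FALSE)
  }
  files <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    stop(sprintf("directory '%s' contains no PNG/TIFF images", source), call. = FALSE)
  }
  if (is.null(fps)) {
    stop("image sequences have no embedded frame rate; supply 'fps'", call. = FALSE)
  }
  frame_seq(lapply(files, .read_one_image), fps = fps)
}

#' Write a frame sequence as numbered PNG images
#'
#' @param fs A [frame_seq()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(fs, dir, prefix = "frame") {
  stopifnot(inherits(fs, "frame_seq"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix, seq_len(fs$n_frames) - 1L))
  for (i in seq_len(fs$n_frames)) {
    png::writePNG(fs$frames[[i]] / 255, paths[i])
  }
  invisible(paths)
}

.trace_columns <- c("label", "time_s", "R", "G", "B",
                    "L", "a", "b", "H", "S", "V", "deltaE")

#' Write colour traces to CSV
#'
#' One row per (ROI, frame) in long format with columns
#' `label, time_s, R, G, B, L, a, b, H, S, V, deltaE`. Reading the file back
#' with [read_traces()] reproduces the trace to at least 6 significant
#' figures.
#'
#' @param traces A `colour_traces` tibble from [extract_traces()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(traces, path) {
  if (!is.data.frame(traces) || nrow(traces) == 0L) {
    stop("'traces' must be a non-empty traces table", call. = FALSE)
  }
  missing <- setdiff(.trace_columns, names(traces))
  if (length(missing)) {
    stop(sprintf("traces table is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  readr::write_csv(traces[, .trace_columns], path)
  invisible(path)
}

#' Read colour traces from CSV
#'
#' @param path CSV written by [write_traces()].
#' @return A `colour_traces` tibble.
#' @export
read_traces <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          label = readr::col_character(),
                          .default = readr::col_double()))
  missing <- setdiff(.trace_columns, names(tr))
  if (length(missing)) {
    stop(sprintf("'%s' is not a traces CSV (missing: %s)", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  class(tr) <- c("colour_traces", class(tr))
  tr
}
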