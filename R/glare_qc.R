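# Glare quantification: per-pixel dispersion in the L*-b* plane.
#
# A well lit, glare-free region has pixels tightly clustered in the
# lightness / blue-yellow plane; specular glare adds a bright, desaturated
# population that widens the scatter. The dispersion scalar makes "tighter
# distribution" testable: the root-mean-square Euclidean distance of the
# (L*, b*) points from their centroid (a* is excluded to stay in the plane
# actually inspected). The scalar definition is this package's own.

#' Pixel-level glare scatter of one ROI
#'
#' Converts every pixel of the mask (not the mean) to CIE-L*a*b* and reports
#' the (L*, b*) point cloud, its centroid, and the RMS dispersion about the
#' centroid. Zero dispersion means all pixels identical in (L*, b*).
#'
#' @param frame H x W x 3 numeric array, channels in `[0, 255]`.
#' @param mask One mask from [build_masks()] (an element of an `roi_masks`
#'   list).
#' @return A `glare_report`: list with `label`, `points` (tibble of `L`,
#'   `b`), `centroid` (named `c(L, b)`), `dispersion`, `n_pixels`.
#' @export
glare_scatter <- function(frame, mask) {
  d <- dim(frame)
  if (length(d) != 3L || d[3L] != 3L) stop("'frame' must be H x W x 3", call. = FALSE)
  px <- mask$pixels
  if (is.null(px) || nrow(px) == 0L) stop("mask has no pixels", call. = FALSE)
  if (any(px[, "row"] >= d[1L]) || any(px[, "col"] >= d[2L])) {
    stop("mask extends beyond the frame", call. = FALSE)
  }
  plane <- d[1L] * d[2L]
  idx <- px[, "row"] + px[, "col"] * d[1L] + 1L
  fv <- as.vector(frame)
  rgb <- cbind(fv[idx], fv[idx + plane], fv[idx + 2L * plane])
  lab <- srgb_to_lab(rgb)
  pts <- lab[, c("L", "b"), drop = FALSE]
  centroid <- colMeans(pts)
  dev <- sweep(pts, 2L, centroid)
  dispersion <- sqrt(mean(rowSums(dev * dev)))
  structure(list(label = mask$label,
                 points = tibble::tibble(L = pts[, "L"], b = pts[, "b"]),
                 centroid = centroid, dispersion = dispersion,
                 n_pixels = nrow(pts)),
            class = "glare_report")
}

#' @export
print.glare_report <- function(x, ...) {
  cat(sprintf("glare report for '%s': %d px, centroid (L* %.2f, b* %.2f), dispersion %.3f\n",
              x$label, x$n_pixels, x$centroid["L"], x$centroid["b"], x$dispersion))
  invisible(x)
}

#' Glare reports for every ROI of a frame
#'
#' @param frame H x W x 3 numeric array.
#' @param masks An `roi_masks` object.
#' @return Named list of `glare_report`s, keyed by label.
#' @export
glare_frame <- function(frame, masks) {
  reps <- lapply(masks, function(m) glare_scatter(frame, m))
  names(reps) <- vapply(masks, `[[`, character(1L), "label")
  reps
}

#' Write glare scatter points to CSV
#'
#' Long format: `label, L, b` for external plotting, plus a per-ROI summary
#' (`label, n_pixels, centroid_L, centroid_b, dispersion`) next to it when
#' `summary_path` is given.
#'
#' @param reports List of `glare_report`s (e.g. from [glare_frame()]).
#' @param path Output CSV for the point cloud.
#' @param summary_path Optional CSV for the per-ROI dispersion summary.
#' @return Invisibly, `path`.
#' @export
write_glare <- function(reports, path, summary_path = NULL) {
  pts <- do.call(rbind, lapply(reports, function(r)
    tibble::tibble(label = r$label, L = r$points$L, b = r$points$b)))
  readr::write_csv(pts, path)
  if (!is.null(summary_path)) {
    smry <- do.call(rbind, lapply(reports, function(r)
      tibble::tibble(label = r$label, n_pixels = r$n_pixels,
                     centroid_L = unname(r$centroid["L"]),
                     centroid_b = unname(r$centroid["b"]),
                     dispersion = r$dispersion)))
    readr::write_csv(smry, summary_path)
  }
  invisible(path)
}
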