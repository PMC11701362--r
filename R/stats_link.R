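# Linking colour kinetics to offline measurements: mutual-information
# ranking of colour channels and the linear delta-E / conversion fit.
#
# The offline series (e.g. HPLC conversion) is sparse (n ~ 5-15) next to
# 25 fps video, so the colour channels are interpolated onto the offline
# sampling times, never the reverse. The MI estimator is equal-frequency
# (quantile) binning with ceiling(sqrt(n)) bins and the plug-in formula;
# rank-based bins make the score invariant under strictly monotone
# transforms of either variable, which is the point of using MI: dependence
# is detected without assuming linearity.

#' External (offline) measurement series
#'
#' @param times Sampling times in seconds, strictly increasing.
#' @param values Measurement values (e.g. HPLC conversion in percent).
#' @return An `external_series` object.
#' @export
external_series <- function(times, values) {
  if (length(times) != length(values)) stop("length mismatch", call. = FALSE)
  if (length(times) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(times) || anyNA(values)) stop("NA values not allowed", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 n = length(times)),
            class = "external_series")
}

#' Read an offline measurement CSV
#'
#' Expects two columns, `time_s` and `value` (header required).
#'
#' @param path CSV path.
#' @return An [external_series()].
#' @export
read_external_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop(sprintf("'%s' must have columns 'time_s' and 'value'", path), call. = FALSE)
  }
  external_series(df$time_s, df$value)
}

#' Interpolate a colour series onto offline sampling times
#'
#' Linear interpolation of `(times, values)` at `at`; every query must lie
#' within the recorded span (no extrapolation).
#'
#' @param times,values The densely sampled colour series.
#' @param at Query times (seconds).
#' @return Numeric vector, `length(at)`.
#' @export
align_series <- function(times, values, at) {
  if (any(at < min(times) - 1e-9) || any(at > max(times) + 1e-9)) {
    stop("offline sampling times fall outside the recorded time span", call. = FALSE)
  }
  stats::approx(times, values, xout = at, method = "linear", ties = "ordered")$y
}

.quantile_bins <- function(v, bins) {
  n <- length(v)
  ceiling(bins * rank(v, ties.method = "first") / n)
}

#' Mutual information by quantile binning
#'
#' Plug-in estimate \eqn{\sum_{ij} p_{ij} \ln[p_{ij} / (p_i p_j)]} on an
#' equal-frequency (rank-based) joint histogram with `bins` bins per
#' variable (default `ceiling(sqrt(n))`). Reported in nats, clamped at 0.
#' Because bins depend only on ranks, the estimate is invariant under
#' strictly monotone transforms of either variable.
#'
#' @param x,y Equal-length numeric vectors, length >= 4.
#' @param bins Bins per variable (default `ceiling(sqrt(length(x)))`).
#' @return Non-negative scalar (nats).
#' @export
mutual_information <- function(x, y, bins = NULL) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (n < 4L) stop("need at least 4 paired samples for MI estimation", call. = FALSE)
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  # a constant variable has zero entropy, hence zero MI (rank-based bins
  # would otherwise spread the ties uniformly)
  if (all(x == x[1L]) || all(y == y[1L])) return(0)
  bx <- .quantile_bins(x, bins)
  by <- .quantile_bins(y, bins)
  joint <- table(factor(bx, levels = seq_len(bins)),
                 factor(by, levels = seq_len(bins))) / n
  px <- rowSums(joint); py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  mi <- sum(terms[joint > 0])
  max(mi, 0)
}

#' Rank colour channels by mutual information with an offline series
#'
#' Each channel of a single ROI's trace is interpolated onto the offline
#' sampling times and scored by [mutual_information()] against the offline
#' values. Scores are normalised by the maximum raw MI so the best channel
#' scores 1; if every channel carries zero MI (e.g. all constant) the
#' normalised scores are all 0. Ties in raw MI break alphabetically by
#' channel name.
#'
#' @param traces A `colour_traces` tibble containing exactly one ROI, or a
#'   multi-ROI table together with `label` naming the ROI to use.
#' @param external An [external_series()].
#' @param channels Channels to rank (default all ten).
#' @param label ROI label to select from a multi-ROI table.
#' @return An `mi_ranking` tibble: `parameter, raw_mi_nats, normalised_mi,
#'   rank`, in descending raw-MI order.
#' @export
rank_parameters <- function(traces, external,
                            channels = c("R", "G", "B", "L", "a", "b",
                                         "H", "S", "V", "deltaE"),
                            label = NULL) {
  stopifnot(inherits(external, "external_series"))
  labs <- unique(traces$label)
  if (is.null(label)) {
    if (length(labs) > 1L) {
      stop("multi-ROI traces: name the ROI with 'label'", call. = FALSE)
    }
    label <- labs
  }
  tr <- traces[traces$label == label, , drop = FALSE]
  if (nrow(tr) == 0L) stop(sprintf("no trace for label '%s'", label), call. = FALSE)
  missing <- setdiff(channels, names(tr))
  if (length(missing)) {
    stop(sprintf("unknown channels: %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  raw <- vapply(channels, function(ch) {
    aligned <- align_series(tr$time_s, tr[[ch]], external$times)
    mutual_information(aligned, external$values)
  }, numeric(1L))
  norm <- if (max(raw) > 0) raw / max(raw) else raw * 0
  ord <- order(-raw, channels)
  out <- tibble::tibble(parameter = channels[ord],
                        raw_mi_nats = unname(raw[ord]),
                        normalised_mi = unname(norm[ord]),
                        rank = seq_along(channels))
  class(out) <- c("mi_ranking", class(out))
  out
}

#' Ordinary least-squares line fit
#'
#' Fits `y = intercept + slope * x` and reports the coefficient of
#' determination. Used for the exemplar linear delta-E / conversion
#' correlation; a constant `y` is reported with slope 0 and r-squared 0 by
#' convention, a constant `x` is an error.
#'
#' @param x,y Equal-length numeric vectors, length >= 2.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("'x' is constant; no line can be fitted", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # r^2 from the residuals directly; summary.lm() warns on exact fits
  r2 <- if (stats::sd(y) == 0) 0 else
    1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(co[2L]), intercept = unname(co[1L]), r_squared = r2)
}
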