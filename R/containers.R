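#' Event table: per-cell list-mode measurements
#'
#' A data frame with one row per acquired event and columns `fsc`
#' (forward scatter), `ssc` (side scatter) and `fl_a` (DNA-stain
#' fluorescence area), all in instrument units on a linear scale. An
#' optional `phase` column carries the latent phase label of simulated
#' events.
#'
#' @param fsc,ssc,fl_a Numeric vectors of equal length; finite, >= 0.
#' @param phase Optional character vector of latent phase labels.
#' @return A data frame of class `c("event_table", "data.frame")`.
#' @export
event_table <- function(fsc, ssc, fl_a, phase = NULL) {
  if (!(length(fsc) == length(ssc) && length(ssc) == length(fl_a)))
    stop("event_table: fsc, ssc, fl_a must have equal length", call. = FALSE)
  vals <- c(fsc, ssc, fl_a)
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0)))
    stop("event_table: channel values must be finite and >= 0", call. = FALSE)
  out <- data.frame(fsc = fsc, ssc = ssc, fl_a = fl_a,
                    stringsAsFactors = FALSE)
  if (!is.null(phase)) {
    if (length(phase) != length(fsc))
      stop("event_table: phase must match event count", call. = FALSE)
    out$phase <- phase
  }
  class(out) <- c("event_table", "data.frame")
  out
}

#' DNA-content histogram
#'
#' Event counts over `n_channels` equal-width fluorescence channels
#' (1024 by default, the classic linear acquisition scale). Bins are
#' left-closed, right-open.
#'
#' @param counts Per-channel counts, all finite and >= 0. Acquired data
#'   are integers; non-integer values are accepted so that continuous
#'   model expectations can be carried in the same container.
#' @param channel_width Fluorescence units per channel.
#' @param origin Fluorescence value at the left edge of channel 1.
#' @return An object of class `dna_histogram` with elements `counts`,
#'   `channel_width`, `origin` and `mids` (channel midpoints, in channel
#'   units used by the cell-cycle fit).
#' @export
dna_histogram <- function(counts, channel_width = 1, origin = 0) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("dna_histogram: counts must be finite and >= 0", call. = FALSE)
  if (channel_width <= 0)
    stop("dna_histogram: channel_width must be positive", call. = FALSE)
  structure(list(
    counts = as.numeric(counts),
    channel_width = channel_width,
    origin = origin,
    mids = origin / channel_width + seq_along(counts) - 0.5
  ), class = "dna_histogram")
}

#' @export
print.dna_histogram <- function(x, ...) {
  cat(sprintf("DNA-content histogram: %d channels (width %g), %d events\n",
              length(x$counts), x$channel_width, sum(x$counts)))
  invisible(x)
}

#' Binned cell-volume distribution
#'
#' Channelyzer-style histogram of cell volumes. Quantiles such as the
#' birth size (10th percentile) are interpolated linearly within bins;
#' the geometric mean uses the count-weighted mean of log bin midpoints.
#'
#' @param edges Strictly increasing bin edges (fl), length `nbins + 1`.
#' @param counts Non-negative counts per bin.
#' @return An object of class `size_distribution`.
#' @export
size_distribution <- function(edges, counts) {
  if (length(edges) != length(counts) + 1)
    stop("size_distribution: need length(edges) == length(counts) + 1",
         call. = FALSE)
  if (any(diff(edges) <= 0))
    stop("size_distribution: edges must be strictly increasing",
         call. = FALSE)
  if (any(counts < 0))
    stop("size_distribution: counts must be >= 0", call. = FALSE)
  structure(list(edges = as.numeric(edges), counts = as.numeric(counts)),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "Cell-volume distribution: %d bins over [%g, %g] fl, %g cells\n",
    length(x$counts), min(x$edges), max(x$edges), sum(x$counts)))
  if (sum(x$counts) > 0)
    cat(sprintf("  geometric mean %.2f fl, 10th percentile %.2f fl\n",
                geometric_mean_size(x), birth_size(x, min_counts = 1)))
  invisible(x)
}

#' Elutriation time course
#'
#' Observations from a synchronous culture of elutriated newborn daughter
#' cells: sampling time, mean cell volume, and the percentage of budded
#' cells (budding marks completion of START).
#'
#' @param time_min Strictly increasing observation times (min).
#' @param mean_volume_fl Mean cell volume at each time (fl).
#' @param pct_budded Percent budded cells at each time, from 0 to 100.
#' @return A data frame of class
#'   `c("elutriation_timecourse", "data.frame")`.
#' @export
elutriation_timecourse <- function(time_min, mean_volume_fl, pct_budded) {
  n <- length(time_min)
  if (length(mean_volume_fl) != n || length(pct_budded) != n)
    stop("elutriation_timecourse: columns must have equal length",
         call. = FALSE)
  if (n && any(diff(time_min) <= 0))
    stop("elutriation_timecourse: times must be strictly increasing",
         call. = FALSE)
  if (n && (any(pct_budded < 0) || any(pct_budded > 100)))
    stop("elutriation_timecourse: pct_budded must lie in [0, 100]",
         call. = FALSE)
  out <- data.frame(time_min = time_min, mean_volume_fl = mean_volume_fl,
                    pct_budded = pct_budded)
  class(out) <- c("elutriation_timecourse", "data.frame")
  out
}
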