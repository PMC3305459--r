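#' Birth size: the 10th percentile of a cell-volume distribution
#'
#' Daughter "birth" size is operationalised as the maximum size of the
#' smallest 10% of cells on the left side of an asynchronous cell-size
#' distribution, i.e. the 10th percentile of the binned volumes, linearly
#' interpolated within the containing bin.
#'
#' @param dist A [size_distribution()].
#' @param p Percentile as a fraction (default 0.1).
#' @param min_counts Minimum total cell count required.
#' @return Volume in fl.
#' @export
birth_size <- function(dist, p = 0.1, min_counts = 100) {
  stopifnot(inherits(dist, "size_distribution"))
  total <- sum(dist$counts)
  if (total == 0)
    stop("birth_size: empty size distribution", call. = FALSE)
  if (total < min_counts)
    stop("birth_size: need at least ", min_counts, " cells", call. = FALSE)
  target <- p * total
  cum <- cumsum(dist$counts)
  i <- which(cum >= target)[1]
  below <- if (i > 1) cum[i - 1] else 0
  frac <- (target - below) / dist$counts[i]
  dist$edges[i] + frac * (dist$edges[i + 1] - dist$edges[i])
}

#' Geometric mean of a cell-volume distribution
#'
#' The exponential of the count-weighted mean of log bin midpoints, the
#' summary recorded for channelyzer size distributions.
#'
#' @param dist A [size_distribution()].
#' @return Volume in fl.
#' @export
geometric_mean_size <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  if (sum(dist$counts) == 0)
    stop("geometric_mean_size: empty size distribution", call. = FALSE)
  mids <- (dist$edges[-1] + dist$edges[-length(dist$edges)]) / 2
  keep <- dist$counts > 0
  exp(sum(dist$counts[keep] * log(mids[keep])) / sum(dist$counts))
}

#' Critical size: volume at which 50% of cells have budded
#'
#' Restricts the budded-vs-size points to the rising portion of the
#' response (by default, points with percent budded in `window` after
#' budding onset), fits an ordinary least-squares line of percent budded
#' against mean volume, and inverts it at 50%. If fewer than two points
#' fall in the window (e.g. a near-step response), the crossing is
#' interpolated linearly between the bracketing observations.
#'
#' @param tc An [elutriation_timecourse()].
#' @param window Percent-budded range defining the rising portion.
#' @param monotone_tol Allowed non-monotonicity (percentage points)
#'   within the rising portion before a quality warning is issued.
#' @return Volume in fl.
#' @export
critical_size <- function(tc, window = c(10, 90), monotone_tol = 5) {
  stopifnot(inherits(tc, "elutriation_timecourse"))
  b <- tc$pct_budded
  v <- tc$mean_volume_fl
  if (max(b) < 50)
    stop("critical_size: percent budded never crosses 50%", call. = FALSE)
  onset <- which(b > window[1])[1]
  rising <- which(b >= window[1] & b <= window[2] &
                    seq_along(b) >= max(onset - 1, 1))
  if (length(rising) >= 2) {
    if (any(diff(b[rising]) < -monotone_tol))
      warning("critical_size: rising portion is non-monotone beyond ",
              monotone_tol, " percentage points", call. = FALSE)
    fit <- stats::lm(b[rising] ~ v[rising])
    slope <- stats::coef(fit)[2]
    if (!is.finite(slope) || slope <= 0)
      stop("critical_size: budded-vs-size fit has non-positive slope",
           call. = FALSE)
    unname((50 - stats::coef(fit)[1]) / slope)
  } else {
    # near-step response: interpolate between the bracketing points
    i <- which(b >= 50)[1]
    if (i == 1) return(v[1])
    unname(v[i - 1] + (50 - b[i - 1]) / (b[i] - b[i - 1]) *
             (v[i] - v[i - 1]))
  }
}

# r^2 of a straight-line fit, robust to zero-variance input
line_r2 <- function(t, resp) {
  if (stats::var(resp) == 0 || stats::var(t) == 0) return(NA_real_)
  stats::cor(t, resp)^2
}

# smallest initial lag whose exclusion brings the fit over the r^2
# threshold (else the r^2-maximising lag), keeping >= 3 points
detect_lag <- function(t, resp, r2_threshold) {
  n <- length(t)
  max_lag <- n - 3L
  r2 <- function(lag) {
    idx <- (lag + 1):n
    line_r2(t[idx], resp[idx])
  }
  r2s <- vapply(0:max_lag, r2, numeric(1))
  if (all(is.na(r2s))) return(0L)          # flat response: no lag to cut
  ok <- which(r2s >= r2_threshold)
  if (length(ok)) ok[1] - 1L else which.max(r2s) - 1L
}

#' Linear growth rate from an elutriation time course
#'
#' Least-squares slope of mean volume against time (fl/min) over the
#' post-lag window. Cultures can take time to recover from elutriation,
#' so an initial "lag" is excluded: the lag is the shortest initial run
#' of points whose removal raises the linear fit's r-squared to at least
#' `r2_threshold` (the r-squared-maximising run if no window reaches it).
#' `lag_points` overrides the automatic choice.
#'
#' @param tc An [elutriation_timecourse()] with at least 4 points.
#' @param r2_threshold Target r-squared for the post-lag fit.
#' @param lag_points Manual override: number of initial points to drop.
#' @return A `growth_fit`: list with `rate_linear` (fl/min), `k_exp`
#'   (`NA` here), `r_squared`, `lag_points_excluded`, `window`
#'   (first/last time used, min) and `model`.
#' @export
growth_rate_linear <- function(tc, r2_threshold = 0.95, lag_points = NULL) {
  stopifnot(inherits(tc, "elutriation_timecourse"))
  if (nrow(tc) < 4)
    stop("growth_rate_linear: need at least 4 points", call. = FALSE)
  t <- tc$time_min
  v <- tc$mean_volume_fl
  lag <- if (is.null(lag_points)) detect_lag(t, v, r2_threshold) else
    as.integer(lag_points)
  idx <- (lag + 1):length(t)
  if (length(idx) < 3)
    stop("growth_rate_linear: fewer than 3 post-lag points", call. = FALSE)
  if (stats::var(v[idx]) == 0)
    stop("growth_rate_linear: no growth (constant volume)", call. = FALSE)
  fit <- stats::lm(v[idx] ~ t[idx])
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0)
    stop("growth_rate_linear: no growth (non-positive slope)",
         call. = FALSE)
  structure(list(rate_linear = slope, k_exp = NA_real_,
                 r_squared = line_r2(t[idx], v[idx]),
                 lag_points_excluded = lag,
                 window = c(t[idx[1]], t[idx[length(idx)]]),
                 model = "linear"),
            class = "growth_fit")
}

#' Exponential growth rate constant from an elutriation time course
#'
#' Least-squares slope of the natural log of mean volume against time in
#' hours: the specific rate of cell-size increase, k (h^-1). Lag handling
#' follows [growth_rate_linear()], applied on the log scale. A constant
#' volume series yields k = 0.
#'
#' @inheritParams growth_rate_linear
#' @return A `growth_fit` with `k_exp` populated (h^-1).
#' @export
growth_rate_exponential <- function(tc, r2_threshold = 0.95,
                                    lag_points = NULL) {
  stopifnot(inherits(tc, "elutriation_timecourse"))
  if (nrow(tc) < 4)
    stop("growth_rate_exponential: need at least 4 points", call. = FALSE)
  if (any(tc$mean_volume_fl <= 0))
    stop("growth_rate_exponential: volumes must be positive",
         call. = FALSE)
  t_h <- tc$time_min / 60
  lv <- log(tc$mean_volume_fl)
  lag <- if (is.null(lag_points)) detect_lag(t_h, lv, r2_threshold) else
    as.integer(lag_points)
  idx <- (lag + 1):length(t_h)
  if (length(idx) < 3)
    stop("growth_rate_exponential: fewer than 3 post-lag points",
         call. = FALSE)
  if (stats::var(lv[idx]) == 0) {
    k <- 0
    r2 <- NA_real_
  } else {
    fit <- stats::lm(lv[idx] ~ t_h[idx])
    k <- unname(stats::coef(fit)[2])
    r2 <- line_r2(t_h[idx], lv[idx])
  }
  structure(list(rate_linear = NA_real_, k_exp = k, r_squared = r2,
                 lag_points_excluded = lag,
                 window = 60 * c(t_h[idx[1]], t_h[idx[length(idx)]]),
                 model = "exponential"),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$model == "linear")
    cat(sprintf("Linear growth: %.4f fl/min", x$rate_linear))
  else
    cat(sprintf("Exponential growth: k = %.4f / h", x$k_exp))
  cat(sprintf(" (r^2 = %.4f, %d lag point(s) excluded, window %g-%g min)\n",
              x$r_squared, x$lag_points_excluded, x$window[1],
              x$window[2]))
  invisible(x)
}

#' Absolute G1 length assuming linear growth
#'
#' `G1 (min) = (critical size - birth size) / growth rate`.
#'
#' @param birth Birth size (fl).
#' @param critical Critical size (fl).
#' @param rate Linear growth rate (fl/min), > 0.
#' @return G1 duration in minutes.
#' @examples
#' g1_length_linear(42.12, 61.53, 0.1)   # 194.1 min
#' @export
g1_length_linear <- function(birth, critical, rate) {
  if (rate <= 0)
    stop("g1_length_linear: rate must be positive", call. = FALSE)
  if (critical < birth)
    stop("g1_length_linear: critical size below birth size", call. = FALSE)
  (critical - birth) / rate
}

#' Absolute G1 length assuming exponential growth
#'
#' `G1 (h) = ln(critical size / birth size) / k`. Invariant under any
#' common rescaling of the two sizes.
#'
#' @param birth Birth size (fl), > 0.
#' @param critical Critical size (fl), >= birth.
#' @param k Specific growth rate constant (h^-1), > 0.
#' @return G1 duration in hours.
#' @export
g1_length_exponential <- function(birth, critical, k) {
  if (k <= 0)
    stop("g1_length_exponential: k must be positive", call. = FALSE)
  if (!(birth > 0) || critical < birth)
    stop("g1_length_exponential: need critical >= birth > 0",
         call. = FALSE)
  log(critical / birth) / k
}

#' Summarise G1 kinetics for one strain
#'
#' Combines a birth-size estimate from an asynchronous volume
#' distribution with critical size and growth rates from an elutriation
#' time course, and derives the absolute G1 length under both growth
#' models.
#'
#' @param dist A [size_distribution()] (asynchronous culture).
#' @param tc An [elutriation_timecourse()].
#' @param ... Passed to the growth-rate fits.
#' @return A `kinetics_summary`: list with `birth_size`, `critical_size`
#'   (fl), `rate_linear` (fl/min), `k_exp` (h^-1), `g1_linear` (min) and
#'   `g1_exponential` (h).
#' @export
kinetics_summary <- function(dist, tc, ...) {
  b <- birth_size(dist)
  cs <- critical_size(tc)
  lin <- growth_rate_linear(tc, ...)
  ex <- growth_rate_exponential(tc, ...)
  structure(list(
    birth_size = b, critical_size = cs,
    rate_linear = lin$rate_linear, k_exp = ex$k_exp,
    g1_linear = g1_length_linear(b, cs, lin$rate_linear),
    g1_exponential = g1_length_exponential(b, cs, ex$k_exp)
  ), class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat("G1 kinetics summary\n")
  cat(sprintf("  birth size    %.2f fl\n", x$birth_size))
  cat(sprintf("  critical size %.2f fl\n", x$critical_size))
  cat(sprintf("  growth rate   %.4f fl/min (linear), k = %.4f /h (exp)\n",
              x$rate_linear, x$k_exp))
  cat(sprintf("  G1 length     %.1f min (linear), %.3f h (exponential)\n",
              x$g1_linear, x$g1_exponential))
  invisible(x)
}

#' Read / write elutriation time courses and size distributions
#'
#' CSV headers: `time_min, mean_volume_fl, pct_budded` for time courses;
#' `volume_fl_edge, count` for size distributions (one more edge row than
#' count rows; the final edge row has an empty count).
#'
#' @param tc An [elutriation_timecourse()].
#' @param dist A [size_distribution()].
#' @param path File path.
#' @return Readers return the corresponding object; writers return
#'   `path` invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "elutriation_timecourse"))
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path)
  elutriation_timecourse(df$time_min, df$mean_volume_fl, df$pct_budded)
}

#' @rdname write_timecourse_csv
#' @export
write_sizedist_csv <- function(dist, path) {
  stopifnot(inherits(dist, "size_distribution"))
  df <- data.frame(volume_fl_edge = dist$edges,
                   count = c(dist$counts, NA))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_sizedist_csv <- function(path) {
  df <- utils::read.csv(path)
  size_distribution(df$volume_fl_edge,
                    df$count[-nrow(df)])
}
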