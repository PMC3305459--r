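#' Dean-Jett-Fox cell-cycle model
#'
#' The univariate DNA-content model fitted to every histogram in the
#' screen: Gaussian G1 and G2/M peaks plus an S-phase component formed by
#' Gaussian-broadening a non-negative quadratic density of DNA content
#' between the two peaks,
#' \deqn{M(x) = A_{G1} N(x; \mu_1, cv_1 \mu_1)
#'            + A_{G2} N(x; \mu_2, cv_2 \mu_2)
#'            + \int_{\mu_1}^{\mu_2} q(u)\, N(x; u, \sigma(u))\, du,}
#' with \eqn{\sigma(u)} interpolated linearly between the G1 and G2 peak
#' standard deviations and \eqn{q} a quadratic, clamped at zero, in the
#' normalised position \eqn{z = (u - \mu_1)/(\mu_2 - \mu_1)}. The S
#' integral is discretised on `n_s` equally spaced DNA contents.
#'
#' Parameters are estimated by bounded Levenberg-Marquardt least squares
#' on the raw channel counts ("without constraints": \eqn{\mu_2} is free
#' rather than fixed at \eqn{2 \mu_1}, and both CVs are free; a minimum
#' peak separation of `min_sep` times \eqn{\mu_1} prevents label
#' swapping). Initialisation is automatic: \eqn{\mu_1} from the global
#' mode, \eqn{\mu_2} from the strongest local mode between 1.5 and 2.5
#' times \eqn{\mu_1} (else \eqn{2\mu_1}), CVs from half-maximum widths.
#'
#' @param hist A [dna_histogram()] with at least 500 events and a clear
#'   mode.
#' @param init Optional manual overrides / constraint hooks: a list with
#'   any of `mu_g1`, `mu_g2`, `cv_g1`, `cv_g2` (starting values, must lie
#'   in the channel range) and optional `lower` / `upper` named bound
#'   overrides on (`mu_g1`, `sep`, `cv_g1`, `cv_g2`).
#' @param n_s Number of discretisation points for the S-phase integral.
#' @param min_sep Minimum \eqn{\mu_2/\mu_1} ratio.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `djf_fit` with the fitted peak positions
#'   and CVs, component areas (`area_g1`, `area_s`, `area_g2`, in
#'   events, each evaluated over the fitted channel range so that a
#'   component pushed outside the data carries no weight), S-phase
#'   quadratic coefficients `s_coeffs` (constant,
#'   linear, quadratic in \eqn{z}), `pct_g1`, `rms`, `converged`,
#'   `n_gated`, the fitted curve and the per-iteration residual trace.
#'   A stalled optimiser returns `converged = FALSE` rather than an
#'   error.
#' @seealso [percent_g1()], [rms_error()], [qc_filter()],
#'   [djf_synthesize()]
#' @export
fit_dean_jett_fox <- function(hist, init = NULL, n_s = 48L, min_sep = 1.3,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200)) {
  stopifnot(inherits(hist, "dna_histogram"))
  y_all <- hist$counts
  if (sum(y_all) < 500)
    stop("unfittable histogram: fewer than 500 events", call. = FALSE)
  if (max(y_all) == min(y_all))
    stop("unfittable histogram: no mode (flat counts)", call. = FALSE)
  nz <- which(y_all > 0)
  fit_range <- nz[1]:nz[length(nz)]
  x <- hist$mids[fit_range]
  y <- as.numeric(y_all[fit_range])

  ys <- runmean(y, 7)
  i_mode <- which.max(ys)
  mode_x <- x[i_mode]
  # the global mode can be either peak (G2/M dominates in many samples):
  # look for a partner mode at ~2x above, then at ~0.5x below
  cand <- local_maxima(ys)
  cand <- cand[ys[cand] > 0.02 * max(ys)]
  above <- cand[x[cand] > 1.5 * mode_x & x[cand] < 2.5 * mode_x]
  below <- cand[x[cand] > mode_x / 2.5 & x[cand] < mode_x / 1.5]
  if (length(above)) {
    mu1 <- mode_x
    mu2 <- x[above[which.max(ys[above])]]
  } else if (length(below)) {
    mu1 <- x[below[which.max(ys[below])]]
    mu2 <- mode_x
  } else {
    mu1 <- mode_x
    mu2 <- 2 * mode_x
  }
  for (ov in c("mu_g1", "mu_g2")) {
    if (!is.null(init[[ov]])) {
      if (init[[ov]] < min(x) || init[[ov]] > max(x))
        stop("fit_dean_jett_fox: init ", ov, " outside channel range",
             call. = FALSE)
      if (ov == "mu_g1") mu1 <- init[[ov]] else mu2 <- init[[ov]]
    }
  }
  i_g1 <- which.min(abs(x - mu1))
  sd1 <- halfmax_sd(x, ys, i_g1)
  cv1 <- min(max(sd1 / mu1, 0.01), 0.25)
  if (!is.null(init$cv_g1)) cv1 <- init$cv_g1
  cv2 <- if (!is.null(init$cv_g2)) init$cv_g2 else cv1
  a1 <- sum(y[abs(x - mu1) < 2 * cv1 * mu1])
  a2 <- sum(y[abs(x - mu2) < 2 * cv2 * mu2])
  as0 <- max(sum(y) - a1 - a2, 0.02 * sum(y))
  v0 <- as0 / max(mu2 - mu1, 1)

  p0 <- c(mu1 = mu1, sep = mu2 / mu1, cv1 = cv1, cv2 = cv2,
          a1 = max(a1, 1), a2 = max(a2, 1), v0 = v0, v1 = v0, v2 = v0)
  lower <- c(mu1 = min(x), sep = min_sep, cv1 = 0.005, cv2 = 0.005,
             a1 = 0, a2 = 0, v0 = 0, v1 = 0, v2 = 0)
  # mu1 may sit anywhere in the data range; mu2 = mu1 * sep may land
  # beyond it (a vanishing G2/M peak), which the area bound handles
  upper <- c(mu1 = max(x), sep = 3, cv1 = 0.3, cv2 = 0.3,
             a1 = Inf, a2 = Inf, v0 = Inf, v1 = Inf, v2 = Inf)
  for (b in names(init$lower)) lower[b] <- init$lower[[b]]
  for (b in names(init$upper)) upper[b] <- init$upper[[b]]
  p0 <- pmin(pmax(p0, lower), upper)

  res_fun <- function(p) djf_components(p, x, n_s)$model - y
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = res_fun, control = control)
  p <- fit$par
  comp <- djf_components(p, x, n_s)
  rms <- sqrt(mean((y - comp$model)^2))
  out <- structure(list(
    mu_g1 = unname(p["mu1"]),
    cv_g1 = unname(p["cv1"]),
    area_g1 = sum(comp$g1),
    mu_g2 = unname(p["mu1"] * p["sep"]),
    cv_g2 = unname(p["cv2"]),
    area_g2 = sum(comp$g2),
    s_coeffs = s_quadratic_coeffs(p),
    area_s = sum(comp$s),
    par = p,
    rms = rms,
    pct_g1 = NA_real_,
    converged = fit$info %in% 1:4,
    n_gated = sum(y_all),
    n_channels = length(y_all),
    fit_range = fit_range,
    fitted = comp$model,
    observed = y,
    mids = x,
    n_s = n_s,
    rss_trace = fit$rsstrace,
    message = fit$message
  ), class = "djf_fit")
  out$pct_g1 <- percent_g1(out)
  out
}

# running mean with edge padding
runmean <- function(y, w) {
  k <- w %/% 2
  yp <- c(rep(y[1], k), y, rep(y[length(y)], k))
  as.numeric(stats::filter(yp, rep(1 / w, w), sides = 2))[k + seq_along(y)]
}

# sd from the full width at half maximum around a mode index
halfmax_sd <- function(x, ys, i_mode) {
  half <- ys[i_mode] / 2
  l <- i_mode
  while (l > 1 && ys[l] >= half) l <- l - 1
  r <- i_mode
  while (r < length(ys) && ys[r] >= half) r <- r + 1
  max((x[r] - x[l]) / 2.355, diff(range(x)) / 200)
}

local_maxima <- function(ys) {
  n <- length(ys)
  if (n < 3) return(integer(0))
  which(ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n]) + 1L
}

# quadratic q(z) through its values at z = 0, 0.5, 1 (all bounded >= 0);
# clamped at zero in between so the S density is non-negative everywhere
s_quadratic_coeffs <- function(p) {
  v0 <- unname(p["v0"]); v1 <- unname(p["v1"]); v2 <- unname(p["v2"])
  c(const = v0, linear = -3 * v0 + 4 * v1 - v2,
    quadratic = 2 * v0 - 4 * v1 + 2 * v2)
}

# evaluate all model components at channel positions x
djf_components <- function(p, x, n_s) {
  mu1 <- p[["mu1"]]
  mu2 <- p[["mu1"]] * p[["sep"]]
  sd1 <- p[["cv1"]] * mu1
  sd2 <- p[["cv2"]] * mu2
  g1 <- p[["a1"]] * stats::dnorm(x, mu1, sd1)
  g2 <- p[["a2"]] * stats::dnorm(x, mu2, sd2)
  z <- (seq_len(n_s) - 0.5) / n_s
  u <- mu1 + z * (mu2 - mu1)
  sd_u <- sd1 + z * (sd2 - sd1)
  cf <- s_quadratic_coeffs(p)
  q <- pmax(cf[1] + cf[2] * z + cf[3] * z^2, 0)
  du <- (mu2 - mu1) / n_s
  s_mat <- outer(x, seq_len(n_s),
                 function(xi, j) stats::dnorm(xi, u[j], sd_u[j]))
  s <- as.numeric(s_mat %*% (q * du))
  list(model = g1 + g2 + s, g1 = g1, g2 = g2, s = s,
       area_s = sum(q) * du)
}

#' Synthesize a noiseless histogram from Dean-Jett-Fox parameters
#'
#' Evaluates the model's expected channel counts, the generative
#' counterpart of [fit_dean_jett_fox()]; useful as a self-consistency
#' oracle and for building test histograms.
#'
#' @param mu_g1,mu_g2 Peak positions (channels).
#' @param cv_g1,cv_g2 Peak coefficients of variation.
#' @param area_g1,area_s,area_g2 Component areas in events (`area_s` is
#'   spread as a flat quadratic unless `s_values` is given).
#' @param s_values Optional values of the S-phase quadratic at
#'   z = 0, 0.5, 1 (overrides `area_s`).
#' @param n_channels Number of channels.
#' @param n_s S-phase discretisation points.
#' @param round_counts Round expected counts to integers (required to
#'   make a valid [dna_histogram()]).
#' @return A [dna_histogram()] of expected (noiseless) counts.
#' @export
djf_synthesize <- function(mu_g1 = 200, mu_g2 = 400, cv_g1 = 0.05,
                           cv_g2 = 0.05, area_g1 = 3100, area_s = 2000,
                           area_g2 = 4900, s_values = NULL,
                           n_channels = 1024L, n_s = 48L,
                           round_counts = TRUE) {
  if (is.null(s_values)) {
    v <- area_s / (mu_g2 - mu_g1)
    s_values <- c(v, v, v)
  }
  p <- c(mu1 = mu_g1, sep = mu_g2 / mu_g1, cv1 = cv_g1, cv2 = cv_g2,
         a1 = area_g1, a2 = area_g2,
         v0 = s_values[1], v1 = s_values[2], v2 = s_values[3])
  x <- seq_len(n_channels) - 0.5
  m <- djf_components(p, x, n_s)$model
  dna_histogram(if (round_counts) round(m) else m, channel_width = 1)
}

#' Percent G1 of a cell-cycle fit
#'
#' The screen statistic: the area of the G1 model peak divided by the
#' combined areas of the G1 and G2/M peaks, times 100. The S-phase area
#' is excluded from the denominator by definition.
#'
#' @param fit A `djf_fit`, or any list with `area_g1` and `area_g2`.
#' @return %G1 between 0 and 100.
#' @export
percent_g1 <- function(fit) {
  a1 <- fit$area_g1
  a2 <- fit$area_g2
  if (is.null(a1) || is.null(a2) || a1 < 0 || a2 < 0)
    stop("percent_g1: needs non-negative area_g1 and area_g2",
         call. = FALSE)
  if (a1 + a2 == 0)
    stop("percent_g1: undefined fraction - both peak areas are zero",
         call. = FALSE)
  100 * a1 / (a1 + a2)
}

#' Root-mean-square residual of a fit against a histogram
#'
#' `sqrt(mean((observed - model)^2))` over the fitted channel range, on
#' raw channel counts. This is the primary fit-quality statistic used to
#' exclude poor model fits.
#'
#' @param fit A `djf_fit`.
#' @param hist The [dna_histogram()] to compare against; must have the
#'   same number of channels the fit was made on.
#' @return The RMS residual.
#' @export
rms_error <- function(fit, hist) {
  stopifnot(inherits(fit, "djf_fit"), inherits(hist, "dna_histogram"))
  if (length(hist$counts) != fit$n_channels)
    stop("rms_error: histogram has ", length(hist$counts),
         " channels but the fit was made on ", fit$n_channels,
         call. = FALSE)
  obs <- hist$counts[fit$fit_range]
  model <- djf_components(fit$par, hist$mids[fit$fit_range], fit$n_s)$model
  sqrt(mean((obs - model)^2))
}

s_values_from_coeffs <- function(cf) {
  unname(c(cf[1], cf[1] + 0.5 * cf[2] + 0.25 * cf[3],
           cf[1] + cf[2] + cf[3]))
}

#' Quality-control filter for cell-cycle fits
#'
#' Applies the screen's exclusion rules: a fit fails when its RMS
#' residual exceeds `rms_max` (default 25), its %G1 falls below `g1_min`
#' (default 5) or above `g1_max` (default 95) - extremes in %G1 usually
#' indicate a poor fit - or the optimiser did not converge. If the
#' histogram is supplied, a `complex_profile` flag marks samples with a
#' prominent secondary mode outside both fitted peaks (e.g. cell
#' separation defects), which were not quantified in the screen.
#'
#' @param fit A `djf_fit`, or any list with `rms` and `pct_g1` (and
#'   optionally `converged`).
#' @param rms_max,g1_min,g1_max QC thresholds.
#' @param hist Optional [dna_histogram()] for the complex-profile check.
#' @param prominence Minimum height of a secondary mode, as a fraction of
#'   the tallest peak, for `complex_profile`.
#' @return A `qc_status`: list with `passed` and `reasons` (a character
#'   vector drawn from `rms_too_high`, `pct_g1_too_low`,
#'   `pct_g1_too_high`, `not_converged`, `complex_profile`); `passed` is
#'   `TRUE` iff `reasons` is empty.
#' @export
qc_filter <- function(fit, rms_max = 25, g1_min = 5, g1_max = 95,
                      hist = NULL, prominence = 0.1) {
  reasons <- character(0)
  if (!is.null(fit$converged) && !isTRUE(fit$converged))
    reasons <- c(reasons, "not_converged")
  if (fit$rms > rms_max) reasons <- c(reasons, "rms_too_high")
  if (fit$pct_g1 < g1_min) reasons <- c(reasons, "pct_g1_too_low")
  if (fit$pct_g1 > g1_max) reasons <- c(reasons, "pct_g1_too_high")
  if (!is.null(hist) && inherits(fit, "djf_fit")) {
    ys <- runmean(as.numeric(hist$counts), 9)
    mx <- local_maxima(ys)
    mids <- hist$mids
    sd1 <- fit$cv_g1 * fit$mu_g1
    sd2 <- fit$cv_g2 * fit$mu_g2
    outside <- mids[mx] < fit$mu_g1 - 3 * sd1 |
      mids[mx] > fit$mu_g2 + 3 * sd2
    peak_height <- max(ys)
    if (any(outside & ys[mx] > prominence * peak_height))
      reasons <- c(reasons, "complex_profile")
  }
  structure(list(passed = length(reasons) == 0, reasons = reasons),
            class = "qc_status")
}

#' @export
print.qc_status <- function(x, ...) {
  if (x$passed) cat("QC: passed\n")
  else cat("QC: failed (", paste(x$reasons, collapse = ", "), ")\n",
           sep = "")
  invisible(x)
}

#' @export
print.djf_fit <- function(x, ...) {
  cat("Dean-Jett-Fox fit\n")
  cat(sprintf("  G1: mu %.1f, CV %.3f, area %.0f\n",
              x$mu_g1, x$cv_g1, x$area_g1))
  cat(sprintf("  G2/M: mu %.1f, CV %.3f, area %.0f\n",
              x$mu_g2, x$cv_g2, x$area_g2))
  cat(sprintf("  S: area %.0f\n", x$area_s))
  cat(sprintf("  %%G1 = %.2f, RMS = %.2f, converged: %s (n = %d)\n",
              x$pct_g1, x$rms, x$converged, x$n_gated))
  invisible(x)
}

#' Fit a DNA-content sample end to end
#'
#' Convenience pipeline: autogate, bin, fit, QC. This is the per-sample
#' path used on every screen measurement.
#'
#' @param events An [event_table()].
#' @param ... Passed to [fit_dean_jett_fox()].
#' @param gate_args,qc_args Named argument lists for [autogate()] and
#'   [qc_filter()].
#' @return A list with `gate`, `hist`, `fit` and `qc`.
#' @export
analyze_sample <- function(events, ..., gate_args = list(),
                           qc_args = list()) {
  gate <- do.call(autogate, c(list(events), gate_args))
  hist <- bin_histogram(gate$retained)
  fit <- fit_dean_jett_fox(hist, ...)
  qc <- do.call(qc_filter, c(list(fit, hist = hist), qc_args))
  list(gate = gate, hist = hist, fit = fit, qc = qc)
}
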