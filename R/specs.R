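#' Specification of a simulated DNA-content population
#'
#' Describes one flow-cytometry sample as a mixture of G1, S, G2/M and
#' sub-G1 debris events on a 1024-channel linear fluorescence scale.
#' The true screen statistic attached to a spec is
#' \code{100 * f_g1 / (f_g1 + f_g2)}: the percentage of cells with an
#' unreplicated genome among the G1 + G2/M pool, with S phase excluded
#' from the denominator.
#'
#' @param f_g1,f_s,f_g2,f_debris Event fractions for the G1 peak, S phase,
#'   G2/M peak and low-signal debris. Must be non-negative and sum to 1.
#' @param mu_g1 G1 peak position, channels on the 0--1023 linear scale.
#' @param g2_ratio Ratio of the G2/M to the G1 peak position
#'   (dimensionless, near 2 for a doubled genome).
#' @param cv_g1,cv_g2 Coefficients of variation of the two fluorescence
#'   peaks, in (0, 0.3).
#' @param n_events Number of list-mode events to draw (10,000 in a typical
#'   acquisition).
#' @param seed Integer seed; all randomness in [simulate_events()] flows
#'   from it.
#' @return An object of class \code{population_spec}.
#' @seealso [wt_population_spec()] for a wild-type-like sample
#'   parameterised by its true %G1, and [simulate_events()].
#' @export
population_spec <- function(f_g1, f_s, f_g2, f_debris = 0,
                            mu_g1 = 300, g2_ratio = 2,
                            cv_g1 = 0.05, cv_g2 = 0.05,
                            n_events = 10000L, seed = 1L) {
  fr <- c(f_g1 = f_g1, f_s = f_s, f_g2 = f_g2, f_debris = f_debris)
  if (any(!is.finite(fr)) || any(fr < 0))
    stop("population_spec: fractions must be finite and >= 0", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("population_spec: f_g1 + f_s + f_g2 + f_debris must equal 1 (got ",
         format(sum(fr)), ")", call. = FALSE)
  if (n_events <= 0)
    stop("population_spec: n_events must be a positive integer", call. = FALSE)
  if (mu_g1 <= 0 || mu_g1 * g2_ratio >= 1024)
    stop("population_spec: peaks must lie on the 0-1023 channel scale",
         call. = FALSE)
  if (g2_ratio <= 1)
    stop("population_spec: g2_ratio must exceed 1", call. = FALSE)
  for (cv in c(cv_g1, cv_g2))
    if (cv <= 0 || cv >= 0.3)
      stop("population_spec: CVs must lie in (0, 0.3)", call. = FALSE)
  structure(list(
    f_g1 = f_g1, f_s = f_s, f_g2 = f_g2, f_debris = f_debris,
    mu_g1 = mu_g1, g2_ratio = g2_ratio, cv_g1 = cv_g1, cv_g2 = cv_g2,
    n_events = as.integer(n_events), seed = as.integer(seed)
  ), class = "population_spec")
}

#' Wild-type-like population spec parameterised by its true %G1
#'
#' Convenience wrapper around [population_spec()]: fixes the S-phase and
#' debris fractions and splits the remainder between G1 and G2/M so that
#' the true %G1 (G1 area over G1 + G2/M areas) equals \code{pct_g1}.
#'
#' @param pct_g1 Target true %G1, in (0, 100).
#' @param f_s,f_debris S-phase and debris fractions.
#' @param ... Passed on to [population_spec()].
#' @return A \code{population_spec}.
#' @export
wt_population_spec <- function(pct_g1 = 31.17, f_s = 0.20, f_debris = 0.09,
                               ...) {
  if (pct_g1 <= 0 || pct_g1 >= 100)
    stop("pct_g1 must lie in (0, 100)", call. = FALSE)
  pool <- 1 - f_s - f_debris
  f_g1 <- pool * pct_g1 / 100
  population_spec(f_g1 = f_g1, f_s = f_s, f_g2 = pool - f_g1,
                  f_debris = f_debris, ...)
}

#' True %G1 implied by a population spec
#'
#' @param spec A \code{population_spec}.
#' @return \code{100 * f_g1 / (f_g1 + f_g2)}.
#' @export
true_pct_g1 <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  100 * spec$f_g1 / (spec$f_g1 + spec$f_g2)
}

#' Specification of a synchronous-culture growth experiment
#'
#' Describes an elutriation time course: a cohort of newborn daughter cells
#' of size \code{birth_size} that, after an optional recovery lag, grows
#' linearly (fl/min) or exponentially (h^-1) and buds once a per-cell size
#' threshold is reached. The per-cell threshold is Gaussian around
#' \code{critical_size} with sd \code{budding_spread}, so 50% of cells have
#' budded exactly at the critical size.
#'
#' @param birth_size Volume at time zero (fl).
#' @param critical_size Volume at which 50% of cells have budded (fl).
#' @param growth_model \code{"linear"} or \code{"exponential"}.
#' @param rate_linear Linear growth rate (fl/min); used when
#'   \code{growth_model == "linear"}.
#' @param k_exp Specific growth rate constant (h^-1); used when
#'   \code{growth_model == "exponential"}.
#' @param budding_spread Standard deviation of the per-cell budding size
#'   threshold (fl).
#' @param lag_min Recovery lag before growth starts (min).
#' @param sample_interval_min Observation spacing (min); cultures were
#'   typically sampled every 20 min.
#' @param noise_sd Measurement noise on observed mean volume (fl).
#' @param seed Integer seed.
#' @return An object of class \code{growth_spec}.
#' @export
growth_spec <- function(birth_size = 42.12, critical_size = 61.53,
                        growth_model = c("linear", "exponential"),
                        rate_linear = 0.1, k_exp = 0.3789,
                        budding_spread = 3, lag_min = 0,
                        sample_interval_min = 20, noise_sd = 0,
                        seed = 1L) {
  growth_model <- match.arg(growth_model)
  if (!(critical_size > birth_size && birth_size > 0))
    stop("growth_spec: need critical_size > birth_size > 0", call. = FALSE)
  if (rate_linear < 0 || k_exp < 0)
    stop("growth_spec: growth rates must be >= 0", call. = FALSE)
  if (sample_interval_min <= 0)
    stop("growth_spec: sample_interval_min must be > 0", call. = FALSE)
  if (budding_spread < 0 || lag_min < 0 || noise_sd < 0)
    stop("growth_spec: budding_spread, lag_min, noise_sd must be >= 0",
         call. = FALSE)
  structure(list(
    birth_size = birth_size, critical_size = critical_size,
    growth_model = growth_model, rate_linear = rate_linear, k_exp = k_exp,
    budding_spread = budding_spread, lag_min = lag_min,
    sample_interval_min = sample_interval_min, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "growth_spec")
}

#' Specification of a simulated deletion screen
#'
#' A screen of \code{n_strains} strains whose per-strain true %G1 is drawn
#' from a wild-type-like null distribution, with \code{n_hits_high} and
#' \code{n_hits_low} strains displaced upward/downward by \code{hit_shift}.
#' Replicate measurements add Gaussian noise of sd \code{replicate_sd}.
#'
#' @param n_strains Number of strains.
#' @param null_mean,null_sd Mean and sd of the null (wild-type-like) %G1
#'   distribution.
#' @param n_hits_high,n_hits_low Counts of strains truly shifted up / down.
#' @param hit_shift Displacement of hit strains' mean %G1.
#' @param replicate_sd Between-replicate measurement noise (sd, %G1).
#' @param n_replicates Replicate measurements per strain.
#' @param seed Integer seed.
#' @return An object of class \code{screen_spec}.
#' @export
screen_spec <- function(n_strains = 4342L, null_mean = 31.17, null_sd = 5.20,
                        n_hits_high = 152L, n_hits_low = 16L, hit_shift = 15,
                        replicate_sd = 2, n_replicates = 1L, seed = 1L) {
  if (n_strains < 0)
    stop("screen_spec: n_strains must be >= 0", call. = FALSE)
  if (n_hits_high + n_hits_low > n_strains)
    stop("screen_spec: n_hits_high + n_hits_low must not exceed n_strains",
         call. = FALSE)
  if (null_sd <= 0 || replicate_sd <= 0)
    stop("screen_spec: null_sd and replicate_sd must be > 0", call. = FALSE)
  if (n_replicates < 1)
    stop("screen_spec: n_replicates must be >= 1", call. = FALSE)
  structure(list(
    n_strains = as.integer(n_strains), null_mean = null_mean,
    null_sd = null_sd, n_hits_high = as.integer(n_hits_high),
    n_hits_low = as.integer(n_hits_low), hit_shift = hit_shift,
    replicate_sd = replicate_sd, n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "screen_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("DNA-content population spec\n")
  cat(sprintf("  fractions: G1 %.3f  S %.3f  G2/M %.3f  debris %.3f\n",
              x$f_g1, x$f_s, x$f_g2, x$f_debris))
  cat(sprintf("  peaks: G1 at %.1f (CV %.3f), G2/M at %.1f (CV %.3f)\n",
              x$mu_g1, x$cv_g1, x$mu_g1 * x$g2_ratio, x$cv_g2))
  cat(sprintf("  true %%G1 = %.2f; %d events, seed %d\n",
              true_pct_g1(x), x$n_events, x$seed))
  invisible(x)
}

#' @export
print.growth_spec <- function(x, ...) {
  cat("Synchronous-culture growth spec\n")
  cat(sprintf("  birth %.2f fl -> critical %.2f fl, %s growth (%s)\n",
              x$birth_size, x$critical_size, x$growth_model,
              if (x$growth_model == "linear")
                sprintf("%.3f fl/min", x$rate_linear)
              else sprintf("k = %.4f / h", x$k_exp)))
  cat(sprintf("  lag %g min, sampled every %g min, volume noise sd %g fl\n",
              x$lag_min, x$sample_interval_min, x$noise_sd))
  invisible(x)
}
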