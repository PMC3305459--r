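#' Simulate one list-mode DNA-content sample
#'
#' Draws `n_events` flow-cytometry events from the mixture described by a
#' [population_spec()]. Each event gets a latent phase (`G1`, `S`, `G2`,
#' `debris`); G1 and G2/M fluorescence are Gaussian peaks at `mu_g1` and
#' `mu_g1 * g2_ratio` with the given CVs; S-phase events carry a DNA
#' content drawn uniformly between the two peak positions (flat S-phase
#' progression) and are blurred with a CV interpolated between the peaks;
#' debris events form an exponential-tailed cluster at low fluorescence
#' and low forward scatter, clearly below the G1 peak. Forward scatter of
#' intact cells increases with DNA content, making FSC a rough size proxy.
#'
#' @param spec A [population_spec()].
#' @return An `event_table`: a data frame with columns `fsc`, `ssc`,
#'   `fl_a` and the latent `phase` label (kept for testing; dropped on
#'   export to FCS). The spec's true %G1 is attached as attribute
#'   `true_pct_g1`.
#' @examples
#' ev <- simulate_events(wt_population_spec(pct_g1 = 31.17, seed = 7))
#' table(ev$phase)
#' @export
simulate_events <- function(spec) {
  if (!inherits(spec, "population_spec"))
    stop("simulate_events: spec must be a population_spec", call. = FALSE)
  n <- spec$n_events
  mu1 <- spec$mu_g1
  mu2 <- spec$mu_g1 * spec$g2_ratio
  sd1 <- spec$cv_g1 * mu1
  sd2 <- spec$cv_g2 * mu2
  withr::with_seed(spec$seed, {
    phase <- sample(c("G1", "S", "G2", "debris"), n, replace = TRUE,
                    prob = c(spec$f_g1, spec$f_s, spec$f_g2, spec$f_debris))
    fl <- numeric(n)
    content <- numeric(n)   # latent DNA content, relative to G1 = 1

    i <- phase == "G1"
    fl[i] <- stats::rnorm(sum(i), mu1, sd1)
    content[i] <- 1

    i <- phase == "G2"
    fl[i] <- stats::rnorm(sum(i), mu2, sd2)
    content[i] <- spec$g2_ratio

    i <- phase == "S"
    if (any(i)) {
      u <- stats::runif(sum(i), mu1, mu2)
      z <- (u - mu1) / (mu2 - mu1)
      sd_u <- sd1 + z * (sd2 - sd1)
      fl[i] <- stats::rnorm(sum(i), u, sd_u)
      content[i] <- u / mu1
    }

    i <- phase == "debris"
    if (any(i)) {
      # truncated exponential, capped at half the G1 peak position
      cap <- 0.5 * mu1
      rate <- 1 / (0.12 * mu1)
      p <- stats::runif(sum(i))
      fl[i] <- -log(1 - p * (1 - exp(-rate * cap))) / rate
      content[i] <- 0
    }
    fl <- pmin(pmax(fl, 0), 1023.9)

    fsc <- numeric(n)
    cells <- phase != "debris"
    fsc[cells] <- 90 * (0.5 + 0.5 * content[cells]) *
      stats::rlnorm(sum(cells), 0, 0.12)
    if (any(!cells))
      fsc[!cells] <- pmin(stats::rexp(sum(!cells), 1 / 8), 40)
    ssc <- 0.6 * fsc * stats::rlnorm(n, 0, 0.2)

    out <- event_table(fsc = fsc, ssc = ssc, fl_a = fl, phase = phase)
    attr(out, "true_pct_g1") <- true_pct_g1(spec)
    out
  })
}

#' Simulate a multi-strain deletion screen
#'
#' Draws a per-strain true mean %G1 (null strains from
#' `Normal(null_mean, null_sd)`; hit strains displaced by `+hit_shift` or
#' `-hit_shift`) and adds replicate measurement noise. Truth labels are
#' kept so that classifier performance can be measured.
#'
#' @param spec A [screen_spec()].
#' @return A `data.frame` with columns `strain`, `true_class`
#'   (`"high_g1"`, `"low_g1"` or `"null"`), `true_mean`, and replicate
#'   columns `rep_1 ... rep_k` (%G1, clamped to (0, 100)).
#' @export
simulate_screen <- function(spec) {
  if (!inherits(spec, "screen_spec"))
    stop("simulate_screen: spec must be a screen_spec", call. = FALSE)
  n <- spec$n_strains
  k <- spec$n_replicates
  if (n == 0L) {
    out <- data.frame(strain = character(0), true_class = character(0),
                      true_mean = numeric(0))
    for (j in seq_len(k)) out[[paste0("rep_", j)]] <- numeric(0)
    return(out)
  }
  withr::with_seed(spec$seed, {
    true_class <- rep("null", n)
    idx <- sample.int(n, spec$n_hits_high + spec$n_hits_low)
    true_class[idx[seq_len(spec$n_hits_high)]] <- "high_g1"
    if (spec$n_hits_low > 0)
      true_class[idx[spec$n_hits_high + seq_len(spec$n_hits_low)]] <- "low_g1"
    shift <- ifelse(true_class == "high_g1", spec$hit_shift,
                    ifelse(true_class == "low_g1", -spec$hit_shift, 0))
    true_mean <- stats::rnorm(n, spec$null_mean, spec$null_sd) + shift
    reps <- matrix(stats::rnorm(n * k, rep(true_mean, k), spec$replicate_sd),
                   nrow = n)
    reps <- pmin(pmax(reps, 0.1), 99.9)
    out <- data.frame(strain = sprintf("strain%05d", seq_len(n)),
                      true_class = true_class, true_mean = true_mean,
                      stringsAsFactors = FALSE)
    for (j in seq_len(k)) out[[paste0("rep_", j)]] <- reps[, j]
    out
  })
}

#' Simulate an elutriation time course
#'
#' Observations at `t = 0, interval, 2*interval, ...`: mean cell volume is
#' constant at `birth_size` during the recovery lag, then grows per the
#' chosen model; the percent of budded cells is
#' `100 * pnorm((size - critical_size) / budding_spread)` at each point
#' (a sigmoidal budded-vs-size response whose 50% crossing sits exactly
#' at the critical size). Gaussian noise of sd `noise_sd` is added to the
#' observed mean volume only.
#'
#' @param spec A [growth_spec()].
#' @param n_points Number of observations; by default the course runs
#'   until budding is essentially complete (capped at 100 points).
#' @return An `elutriation_timecourse`: a data frame with columns
#'   `time_min`, `mean_volume_fl`, `pct_budded`.
#' @export
simulate_elutriation <- function(spec, n_points = NULL) {
  if (!inherits(spec, "growth_spec"))
    stop("simulate_elutriation: spec must be a growth_spec", call. = FALSE)
  dt <- spec$sample_interval_min
  if (is.null(n_points)) {
    # run until the size exceeds critical + 4 spreads (budding ~complete)
    target <- spec$critical_size + max(4 * spec$budding_spread, 2)
    t_end <- if (spec$growth_model == "linear") {
      if (spec$rate_linear > 0)
        spec$lag_min + (target - spec$birth_size) / spec$rate_linear
      else 10 * dt
    } else {
      if (spec$k_exp > 0)
        spec$lag_min + 60 * log(target / spec$birth_size) / spec$k_exp
      else 10 * dt
    }
    n_points <- min(100L, max(6L, ceiling(t_end / dt) + 2L))
  }
  time_min <- seq(0, by = dt, length.out = n_points)
  t_grow <- pmax(time_min - spec$lag_min, 0)
  size <- if (spec$growth_model == "linear") {
    spec$birth_size + spec$rate_linear * t_grow
  } else {
    spec$birth_size * exp(spec$k_exp * t_grow / 60)
  }
  pct_budded <- if (spec$budding_spread > 0) {
    100 * stats::pnorm((size - spec$critical_size) / spec$budding_spread)
  } else {
    100 * as.numeric(size >= spec$critical_size)
  }
  obs <- if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed,
                     size + stats::rnorm(n_points, 0, spec$noise_sd))
  } else size
  elutriation_timecourse(time_min = time_min, mean_volume_fl = obs,
                         pct_budded = pct_budded)
}

#' Simulate an asynchronous cell-volume distribution
#'
#' Emulates channelyzer output: draws cell volumes from a chosen
#' distribution and bins them into a volume histogram with known analytic
#' quantiles, for birth-size and geometric-mean estimation.
#'
#' @param mode `"lognormal"` (params `meanlog`, `sdlog`, or `p10` +
#'   `sdlog`, in which case `meanlog` is solved so the analytic 10th
#'   percentile equals `p10`), `"uniform"` (params `min`, `max`), or
#'   `"empirical"` (param `volumes`: a numeric vector binned as-is).
#' @param params Named list of distribution parameters (see `mode`).
#' @param n Number of cells to draw (ignored for `"empirical"`).
#' @param bin_width Width of the volume bins (fl).
#' @param seed Integer seed.
#' @return A [size_distribution()].
#' @examples
#' d <- simulate_size_distribution("uniform", list(min = 0, max = 100),
#'                                 n = 5e4, seed = 3)
#' birth_size(d)   # ~10 fl
#' @export
simulate_size_distribution <- function(mode = c("lognormal", "uniform",
                                                "empirical"),
                                       params = list(), n = 20000L,
                                       bin_width = 1, seed = 1L) {
  mode <- match.arg(mode)
  vols <- withr::with_seed(as.integer(seed), switch(
    mode,
    lognormal = {
      sdlog <- params$sdlog %||% 0.35
      meanlog <- if (!is.null(params$p10)) {
        if (params$p10 <= 0) stop("p10 must be positive", call. = FALSE)
        log(params$p10) - stats::qnorm(0.1) * sdlog
      } else params$meanlog %||% log(50)
      stats::rlnorm(n, meanlog, sdlog)
    },
    uniform = {
      lo <- params$min %||% 0
      hi <- params$max %||% 100
      if (lo < 0 || hi <= lo)
        stop("uniform mode needs 0 <= min < max", call. = FALSE)
      stats::runif(n, lo, hi)
    },
    empirical = {
      v <- params$volumes
      if (is.null(v) || !length(v))
        stop("empirical mode needs params$volumes", call. = FALSE)
      v
    }
  ))
  if (any(vols <= 0))
    stop("simulate_size_distribution: volumes must be positive", call. = FALSE)
  edges <- seq(0, ceiling(max(vols) / bin_width) * bin_width + bin_width,
               by = bin_width)
  counts <- as.integer(table(cut(vols, edges, right = FALSE,
                                 include.lowest = FALSE)))
  size_distribution(edges = edges, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
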