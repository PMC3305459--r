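test_that("birth size is the interpolated 10th percentile", {
  u <- size_distribution(0:100, rep(10, 100))
  expect_equal(birth_size(u), 10)
  # within a single occupied bin the value interpolates inside that bin
  one <- size_distribution(c(49, 51), 500)
  expect_equal(birth_size(one), 49 + 0.1 * 2)

  ln <- simulate_size_distribution("lognormal",
                                   list(p10 = 42.12, sdlog = 0.35),
                                   n = 200000, bin_width = 0.5, seed = 9)
  expect_lt(abs(birth_size(ln) - 42.12), 0.5)

  expect_error(birth_size(size_distribution(0:10, rep(5, 10))),
               "at least 100")
  expect_error(birth_size(size_distribution(0:10, rep(0, 10))), "empty")
})

test_that("geometric mean size matches closed forms", {
  expect_equal(geometric_mean_size(size_distribution(c(49, 51), 1000)), 50)
  two <- size_distribution(c(24, 26, 99, 101), c(500, 0, 500))
  expect_equal(geometric_mean_size(two), sqrt(25 * 100))

  ln <- simulate_size_distribution("lognormal",
                                   list(meanlog = log(50), sdlog = 0.3),
                                   n = 200000, bin_width = 0.5, seed = 10)
  expect_lt(abs(geometric_mean_size(ln) - 50), 0.5)
})

test_that("critical size inverts the rising budded response at 50%", {
  # exactly linear response: 0% at 50 fl rising to 100% at 70 fl
  v <- seq(40, 80, by = 2)
  b <- pmin(pmax((v - 50) * 5, 0), 100)
  tc <- elutriation_timecourse(seq_along(v) * 20, v, b)
  expect_equal(critical_size(tc), 60, tolerance = 1e-9)

  sim <- simulate_elutriation(growth_spec(birth_size = 42.12,
                                          critical_size = 61.53,
                                          rate_linear = 0.1,
                                          budding_spread = 3,
                                          noise_sd = 0))
  expect_lt(abs(critical_size(sim) - 61.53), 0.2)

  # a near-step response falls back to bracketing interpolation
  step <- simulate_elutriation(growth_spec(birth_size = 40,
                                           critical_size = 60,
                                           rate_linear = 0.1,
                                           budding_spread = 0,
                                           noise_sd = 0))
  expect_lt(abs(critical_size(step) - 60), 2)

  flat <- elutriation_timecourse(c(0, 20, 40), c(40, 42, 44), c(0, 5, 10))
  expect_error(critical_size(flat), "never crosses 50")
})

test_that("the linear growth rate is exact on noiseless data, with lag handling", {
  tc <- simulate_elutriation(growth_spec(birth_size = 42, critical_size = 62,
                                         rate_linear = 0.1, noise_sd = 0))
  fit <- growth_rate_linear(tc)
  expect_equal(fit$rate_linear, 0.1, tolerance = 1e-12)
  expect_equal(fit$lag_points_excluded, 0)
  expect_equal(fit$r_squared, 1)

  # a flat prefix is detected and excluded as lag
  lagged <- elutriation_timecourse(seq(0, 300, by = 60),
                                   c(42, 42, 42, 48, 54, 60),
                                   rep(0, 6))
  lf <- growth_rate_linear(lagged)
  expect_equal(lf$lag_points_excluded, 2)
  expect_equal(lf$rate_linear, 0.1, tolerance = 1e-12)
  # the manual override wins
  expect_equal(growth_rate_linear(lagged,
                                  lag_points = 3)$lag_points_excluded, 3)

  const <- elutriation_timecourse(c(0, 20, 40, 60), rep(50, 4), rep(0, 4))
  expect_error(growth_rate_linear(const), "constant volume")
  shrink <- elutriation_timecourse(c(0, 20, 40, 60), c(60, 55, 50, 45),
                                   rep(0, 4))
  expect_error(growth_rate_linear(shrink), "non-positive slope")
  expect_error(growth_rate_linear(lagged[1:3, ]), "at least 4")
})

test_that("the exponential rate constant is exact on noiseless data", {
  tc <- simulate_elutriation(growth_spec(birth_size = 42.12,
                                         critical_size = 61.53,
                                         growth_model = "exponential",
                                         k_exp = 0.3789, noise_sd = 0))
  fit <- growth_rate_exponential(tc)
  expect_equal(fit$k_exp, 0.3789, tolerance = 1e-9)
  expect_equal(fit$lag_points_excluded, 0)

  const <- elutriation_timecourse(c(0, 20, 40, 60), rep(50, 4), rep(0, 4))
  expect_equal(growth_rate_exponential(const)$k_exp, 0)
  bad <- elutriation_timecourse(c(0, 20, 40, 60), c(50, 0, 50, 60),
                                rep(0, 4))
  expect_error(growth_rate_exponential(bad), "positive")

  # on truly linear data the linear model explains the course better
  lin <- simulate_elutriation(growth_spec(birth_size = 30,
                                          critical_size = 90,
                                          rate_linear = 0.2, noise_sd = 0))
  rl <- growth_rate_linear(lin, lag_points = 0)
  re <- growth_rate_exponential(lin, lag_points = 0)
  expect_gt(rl$r_squared, re$r_squared)
})

test_that("G1 length formulas follow their definitions and scale laws", {
  expect_equal(g1_length_linear(42.12, 61.53, 0.1), 194.1, tolerance = 1e-9)
  expect_equal(g1_length_linear(50, 50, 0.1), 0)
  expect_error(g1_length_linear(50, 60, 0), "positive")
  expect_error(g1_length_linear(60, 50, 0.1), "critical size below")

  expect_equal(g1_length_exponential(42.12, 61.53, 0.3789),
               log(61.53 / 42.12) / 0.3789)
  expect_lt(abs(g1_length_exponential(42.12, 61.53, 0.3789) - 1), 0.005)
  expect_error(g1_length_exponential(42.12, 61.53, 0), "positive")
  expect_error(g1_length_exponential(0, 61.53, 0.3), "critical >= birth")

  # linear G1 scales inversely with the rate; exponential G1 is invariant
  # under a common rescaling of the two sizes
  expect_equal(g1_length_linear(40, 60, 0.2),
               g1_length_linear(40, 60, 0.1) / 2)
  expect_equal(g1_length_exponential(80, 120, 0.3),
               g1_length_exponential(40, 60, 0.3), tolerance = 1e-12)
})

test_that("the full kinetics pipeline recovers a noiseless strain, lag included", {
  dist <- simulate_size_distribution("lognormal",
                                     list(p10 = 42.12, sdlog = 0.3),
                                     n = 200000, bin_width = 0.5, seed = 21)
  tc <- simulate_elutriation(growth_spec(birth_size = 42.12,
                                         critical_size = 61.53,
                                         rate_linear = 0.1, lag_min = 40,
                                         budding_spread = 3, noise_sd = 0))
  ks <- kinetics_summary(dist, tc, r2_threshold = 0.9999)
  expect_lt(abs(ks$birth_size - 42.12), 0.5)
  expect_lt(abs(ks$critical_size - 61.53), 0.3)
  expect_lt(abs(ks$rate_linear - 0.1), 1e-6)
  expect_lt(abs(ks$g1_linear - 194.1), 8)
})

test_that("a strict threshold makes the rate insensitive to a flat lag prefix", {
  fits <- lapply(c(0, 40, 80), function(lag) {
    tc <- simulate_elutriation(growth_spec(birth_size = 42,
                                           critical_size = 62,
                                           rate_linear = 0.1,
                                           lag_min = lag, noise_sd = 0))
    growth_rate_linear(tc, r2_threshold = 0.9999)
  })
  rates <- vapply(fits, `[[`, numeric(1), "rate_linear")
  expect_lt(max(abs(rates - 0.1)), 1e-9)
  expect_equal(vapply(fits, `[[`, numeric(1), "lag_points_excluded"),
               c(0, 2, 4))
})

test_that("time courses and size distributions round trip through CSV", {
  tc <- simulate_elutriation(growth_spec(noise_sd = 0.3, seed = 8))
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(tc, p1)
  back <- read_timecourse_csv(p1)
  expect_equal(back$mean_volume_fl, tc$mean_volume_fl, tolerance = 1e-9)
  expect_equal(back$pct_budded, tc$pct_budded, tolerance = 1e-9)

  dist <- simulate_size_distribution("lognormal",
                                     list(p10 = 40, sdlog = 0.3),
                                     n = 5000, seed = 12)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sizedist_csv(dist, p2)
  back2 <- read_sizedist_csv(p2)
  expect_equal(back2$edges, dist$edges)
  expect_equal(back2$counts, dist$counts)
})
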