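test_that("the wild-type reference yields the 2-sd cutoffs", {
  ref <- fit_reference(exact_moments(250, 31.17, 5.20))
  expect_equal(ref$mean, 31.17, tolerance = 1e-10)
  expect_equal(ref$sd, 5.20, tolerance = 1e-10)
  expect_equal(ref$cutoff_low, 20.77, tolerance = 1e-9)
  expect_equal(ref$cutoff_high, 41.57, tolerance = 1e-9)
  expect_equal(ref$cutoff_high - ref$cutoff_low, 4 * ref$sd)

  const <- fit_reference(c(30, 30, 30))
  expect_equal(const$cutoff_low, 30)
  expect_equal(const$cutoff_high, 30)
  r2 <- fit_reference(exact_moments(50, 50, 10))
  expect_equal(c(r2$cutoff_low, r2$cutoff_high), c(30, 70))

  expect_error(fit_reference(31), "at least 2")
  expect_error(fit_reference(c(-5, 40)), "0, 100")
})

test_that("strains are classified by strict 2-sd rules", {
  ref <- fit_reference(exact_moments(250, 31.17, 5.20))
  expect_equal(classify_strain(54, ref), "high_g1")
  expect_equal(classify_strain(25, ref), "wt_like")
  expect_equal(classify_strain(31.17, ref), "wt_like")
  # boundary values stay wild-type-like (strict inequalities)
  expect_equal(classify_strain(ref$cutoff_high, ref), "wt_like")
  expect_equal(classify_strain(ref$cutoff_low, ref), "wt_like")
  expect_error(classify_strain(NA_real_, ref), "missing")
  # monotone in the final %G1
  lab <- classify_strain(seq(1, 99, by = 0.5), ref)
  codes <- c(low_g1 = 1, wt_like = 2, high_g1 = 3)
  expect_true(all(diff(codes[lab]) >= 0))
})

test_that("replicates are aggregated and flagged per the repeat policy", {
  ref <- fit_reference(exact_moments(250, 31.17, 5.20))
  r <- finalize_replicates(c(45, 47), ref)
  expect_equal(r$final, 46)
  expect_equal(r$classification, "high_g1")
  expect_false(r$repeat_flag)

  one <- finalize_replicates(43, ref, min_repeats = 2)
  expect_true(one$repeat_flag)

  wt <- finalize_replicates(c(30, 32, 31), ref)
  expect_equal(wt$final, 31)
  expect_equal(wt$classification, "wt_like")

  none <- finalize_replicates(numeric(0), ref)
  expect_equal(none$classification, "excluded")
  expect_true(is.na(none$final))

  med <- finalize_replicates(c(30, 32, 40), ref, agg = "median")
  expect_equal(med$final, 32)
})

test_that("spearman matches a brute-force rank-then-Pearson oracle", {
  expect_equal(spearman(1:10, (1:10)^3), 1)
  expect_equal(spearman(1:10, rev(1:10)), -1)

  x <- c(1, 2, 2, 4, 5, 6)
  y <- c(3, 1, 4, 4, 6, 5)
  expect_equal(spearman(x, y), spearman_oracle(x, y), tolerance = 1e-12)

  set.seed(41)
  for (i in 1:20) {
    a <- sample(1:8, 30, replace = TRUE)
    b <- rnorm(30)
    expect_equal(spearman(a, b), spearman_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(spearman(c(1, 2, NA), c(1, NA, 3)), "3 complete pairs")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(42)
  x <- rnorm(50)
  y <- x + rnorm(50)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y), base, tolerance = 1e-12)
  expect_equal(spearman(x, y^3), base, tolerance = 1e-12)
  expect_equal(spearman(rank(x), 2 * y + 7), base, tolerance = 1e-12)
})

test_that("screen-wide correlations handle missingness and subgroups", {
  sc <- simulate_screen(screen_spec(n_strains = 4000, n_hits_high = 0,
                                    n_hits_low = 0, seed = 30))
  sc$neg <- -sc$rep_1
  expect_equal(correlate_screen(sc, "rep_1", "neg")$rho, -1)

  sc$indep <- withr::with_seed(77, rnorm(4000))
  r <- correlate_screen(sc, "rep_1", "indep")
  expect_lt(abs(r$rho), 0.05)
  expect_equal(r$n_used, 4000)

  sc$indep[1:100] <- NA
  expect_equal(correlate_screen(sc, "rep_1", "indep")$n_used, 3900)
  expect_error(correlate_screen(sc, "rep_1", "nope"), "unknown column")

  ref <- fit_reference(exact_moments(250, 31.17, 5.20))
  sc <- classify_screen(sc, ref)
  sub <- correlate_screen(sc, "final_pct_g1", "indep",
                          subgroup = "high_g1")
  expect_equal(sub$n_used, sum(sc$classification == "high_g1" &
                                 is.finite(sc$indep)))
})

test_that("Welch comparisons match the closed form, from raw data or summaries", {
  w <- compare_groups(summary_a = c(42.12, 1.23, 3),
                      summary_b = c(16.04, 0.62, 3))
  o <- welch_oracle(42.12, 1.23, 3, 16.04, 0.62, 3)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)
  expect_equal(w$t, 32.8, tolerance = 0.01)
  expect_equal(w$df, 2.9, tolerance = 0.05)

  set.seed(55)
  a <- rnorm(12, 10, 2)
  b <- rnorm(9, 12, 3)
  raw <- compare_groups(a, b)
  summ <- compare_groups(summary_a = c(mean(a), sd(a), 12),
                         summary_b = c(mean(b), sd(b), 9))
  expect_equal(raw$t, summ$t, tolerance = 1e-9)
  expect_equal(raw$df, summ$df, tolerance = 1e-9)
  # and both agree with stats::t.test
  tt <- t.test(a, b)
  expect_equal(raw$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(raw$df, unname(tt$parameter), tolerance = 1e-9)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  apart <- compare_groups(a, a + 1000)
  expect_lt(apart$p, 1e-6)
})

test_that("box summaries follow the 1.5-IQR whisker rule", {
  v <- c(1, 2, 3, 4, 5, 100)
  w <- compare_groups(v, v + 1)
  b <- w$box_a
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  expect_equal(b$q1, q[1])
  expect_equal(b$q3, q[2])
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 5)   # 100 is beyond q3 + 1.5 IQR
  expect_equal(b$outliers, 100)
})

test_that("an all-null screen flags ~4.55% of strains at the 2-sd cutoffs", {
  sc <- simulate_screen(screen_spec(n_strains = 10000, n_hits_high = 0,
                                    n_hits_low = 0, null_mean = 31.17,
                                    null_sd = 5.20, replicate_sd = 1e-6,
                                    seed = 61))
  ref <- fit_reference(exact_moments(2000, 31.17, 5.20))
  sc <- classify_screen(sc, ref)
  flagged <- mean(sc$classification != "wt_like")
  p <- 2 * pnorm(-2)
  expect_lt(abs(flagged - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("screen tables round trip as TSV and CSV", {
  sc <- simulate_screen(screen_spec(n_strains = 20, n_hits_high = 2,
                                    n_hits_low = 1, seed = 3))
  for (ext in c(".tsv", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_screen_table(sc, path)
    back <- read_screen_table(path)
    expect_equal(back$rep_1, sc$rep_1, tolerance = 1e-9)
    expect_identical(back$strain, sc$strain)
  }
})
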