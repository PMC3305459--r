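# values with exactly the requested sample mean and sd (n-1 divisor)
exact_moments <- function(n, mean, sd, seed = 1) {
  z <- withr::with_seed(seed, stats::rnorm(n))
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# closed-form Welch t, df and two-tailed p from (mean, sd, n) summaries
welch_oracle <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# rank-then-Pearson Spearman oracle with average ranks for ties
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# one pass of the full per-sample pipeline, returning the fitted %G1
fit_sample_pct_g1 <- function(true_pct, seed, ...) {
  ev <- simulate_events(wt_population_spec(pct_g1 = true_pct, seed = seed,
                                           ...))
  a <- analyze_sample(ev)
  a$fit$pct_g1
}
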