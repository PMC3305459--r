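#' Wild-type reference distribution for %G1
#'
#' Fits a normal distribution to wild-type %G1 measurements (sample mean
#' and sd with the n-1 divisor, the Gaussian fit up to the divisor
#' convention) and derives the screen's classification cutoffs at two
#' standard deviations either side of the mean.
#'
#' @param wt_values Wild-type %G1 values, each finite and in (0, 100);
#'   at least 2 required.
#' @return A `reference_distribution`: list with `mean`, `sd`, `n`,
#'   `cutoff_low` (= mean - 2 sd) and `cutoff_high` (= mean + 2 sd).
#' @examples
#' ref <- fit_reference(c(28.4, 31.2, 33.9, 30.1))
#' ref$cutoff_low; ref$cutoff_high
#' @export
fit_reference <- function(wt_values) {
  wt_values <- wt_values[is.finite(wt_values)]
  if (length(wt_values) < 2)
    stop("fit_reference: need at least 2 finite wild-type values",
         call. = FALSE)
  if (any(wt_values <= 0 | wt_values >= 100))
    stop("fit_reference: %G1 values must lie in (0, 100)", call. = FALSE)
  m <- mean(wt_values)
  s <- stats::sd(wt_values)
  structure(list(mean = m, sd = s, n = length(wt_values),
                 cutoff_low = m - 2 * s, cutoff_high = m + 2 * s),
            class = "reference_distribution")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("Wild-type %%G1 reference: %.2f +/- %.2f (n = %d)\n",
              x$mean, x$sd, x$n))
  cat(sprintf("  2-sd cutoffs: Low G1 < %.2f, High G1 > %.2f\n",
              x$cutoff_low, x$cutoff_high))
  invisible(x)
}

#' Classify a strain's final %G1 against the wild-type reference
#'
#' Strains whose %G1 is greater or less than two standard deviations of
#' the wild-type distribution differ significantly from wild type:
#' above `cutoff_high` is `"high_g1"`, below `cutoff_low` is `"low_g1"`,
#' anything else (including values exactly at a cutoff - the rule uses
#' strict inequalities) is `"wt_like"`.
#'
#' @param final_pct_g1 Final %G1 value(s); vectorised.
#' @param ref A [fit_reference()] result.
#' @return Character vector of labels.
#' @export
classify_strain <- function(final_pct_g1, ref) {
  stopifnot(inherits(ref, "reference_distribution"))
  if (any(is.na(final_pct_g1)))
    stop("classify_strain: missing %G1 value", call. = FALSE)
  ifelse(final_pct_g1 > ref$cutoff_high, "high_g1",
         ifelse(final_pct_g1 < ref$cutoff_low, "low_g1", "wt_like"))
}

#' Aggregate replicate %G1 measurements for one strain
#'
#' The final %G1 is the unweighted mean (or median) of the QC-passing
#' replicates. Measurements falling outside the wild-type cutoffs were
#' repeated additional times in the screen, so a `repeat_flag` is raised
#' when any single replicate lies outside the cutoffs but fewer than
#' `min_repeats` replicates are available.
#'
#' @param replicates Numeric %G1 replicate values that passed QC.
#' @param ref A [fit_reference()] result.
#' @param min_repeats Required replicate count for strains with any
#'   out-of-cutoff measurement.
#' @param agg `"mean"` (default) or `"median"`.
#' @return List with `final` (%G1), `classification`, `repeat_flag`,
#'   `n_replicates`; or classification `"excluded"` (with `final = NA`)
#'   when no replicate passed QC.
#' @export
finalize_replicates <- function(replicates, ref, min_repeats = 2L,
                                agg = c("mean", "median")) {
  stopifnot(inherits(ref, "reference_distribution"))
  agg <- match.arg(agg)
  replicates <- replicates[is.finite(replicates)]
  if (!length(replicates))
    return(list(final = NA_real_, classification = "excluded",
                repeat_flag = FALSE, n_replicates = 0L))
  final <- if (agg == "mean") mean(replicates) else
    stats::median(replicates)
  outside <- replicates > ref$cutoff_high | replicates < ref$cutoff_low
  list(final = final,
       classification = classify_strain(final, ref),
       repeat_flag = any(outside) && length(replicates) < min_repeats,
       n_replicates = length(replicates))
}

#' Classify every strain in a screen table
#'
#' Applies [finalize_replicates()] and [classify_strain()] across a
#' screen table with replicate columns `rep_1 ... rep_k` (as produced by
#' [simulate_screen()]) or a single `pct_g1` column.
#'
#' @param table Screen data frame.
#' @param ref A [fit_reference()] result.
#' @param ... Passed to [finalize_replicates()].
#' @return The table with added columns `final_pct_g1`, `classification`
#'   and `repeat_flag`.
#' @export
classify_screen <- function(table, ref, ...) {
  rep_cols <- grep("^rep_[0-9]+$", names(table), value = TRUE)
  if (!length(rep_cols)) {
    if (is.null(table$pct_g1))
      stop("classify_screen: no rep_* or pct_g1 columns", call. = FALSE)
    rep_cols <- "pct_g1"
  }
  res <- lapply(seq_len(nrow(table)), function(i) {
    finalize_replicates(as.numeric(table[i, rep_cols]), ref, ...)
  })
  table$final_pct_g1 <- vapply(res, `[[`, numeric(1), "final")
  table$classification <- vapply(res, `[[`, character(1), "classification")
  table$repeat_flag <- vapply(res, `[[`, logical(1), "repeat_flag")
  table
}

#' Spearman rank correlation
#'
#' Non-parametric rank correlation with average ranks for ties. Pairs
#' with a missing entry are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @return Spearman's rho.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y))
    stop("spearman: x and y must be paired", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3)
    stop("spearman: fewer than 3 complete pairs", call. = FALSE)
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Screen-wide rank correlation between two columns
#'
#' Spearman correlation over complete pairs of two screen-table columns,
#' optionally restricted to a classification subgroup (e.g. the High G1
#' group), as used to compare %G1 against external cell-size and
#' fitness datasets.
#'
#' @param table Screen data frame.
#' @param x_col,y_col Column names.
#' @param subgroup Optional classification label to restrict to
#'   (requires a `classification` column).
#' @return List with `rho` and `n_used`.
#' @export
correlate_screen <- function(table, x_col, y_col, subgroup = NULL) {
  for (col in c(x_col, y_col))
    if (is.null(table[[col]]))
      stop("correlate_screen: unknown column '", col, "'", call. = FALSE)
  if (!is.null(subgroup)) {
    if (is.null(table$classification))
      stop("correlate_screen: no classification column for subgroup",
           call. = FALSE)
    table <- table[table$classification == subgroup, , drop = FALSE]
  }
  x <- table[[x_col]]
  y <- table[[y_col]]
  ok <- is.finite(x) & is.finite(y)
  list(rho = spearman(x[ok], y[ok]), n_used = sum(ok))
}

#' Welch two-sample comparison
#'
#' Two-tailed t test assuming unequal variances (Welch-Satterthwaite
#' degrees of freedom), from raw values or from printed summary
#' statistics (mean, sd, n per group), plus a Tukey box-plot summary of
#' each raw group (quartiles, whiskers at the most extreme datum within
#' 1.5 interquartile ranges of the box, outliers beyond).
#'
#' @param values_a,values_b Raw group values (optional if summaries are
#'   given).
#' @param summary_a,summary_b Alternative summary input: numeric vectors
#'   `c(mean, sd, n)`.
#' @return List with `t`, `df`, `p`, group summaries, and (for raw
#'   input) `box_a` / `box_b`.
#' @examples
#' compare_groups(summary_a = c(42.12, 1.23, 3),
#'                summary_b = c(16.04, 0.62, 3))
#' @export
compare_groups <- function(values_a = NULL, values_b = NULL,
                           summary_a = NULL, summary_b = NULL) {
  summarize <- function(v, s, which) {
    if (!is.null(v)) {
      v <- v[is.finite(v)]
      if (length(v) < 2)
        stop("compare_groups: group ", which,
             " needs n >= 2 raw values (or summary statistics)",
             call. = FALSE)
      list(mean = mean(v), sd = stats::sd(v), n = length(v),
           box = box_summary(v))
    } else if (!is.null(s)) {
      if (length(s) != 3 || s[3] < 2 || s[2] < 0)
        stop("compare_groups: summary must be c(mean, sd >= 0, n >= 2)",
             call. = FALSE)
      list(mean = s[1], sd = s[2], n = s[3], box = NULL)
    } else {
      stop("compare_groups: group ", which, " missing", call. = FALSE)
    }
  }
  a <- summarize(values_a, summary_a, "a")
  b <- summarize(values_b, summary_b, "b")
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se <- sqrt(va + vb)
  if (se == 0)
    stop("compare_groups: both groups have zero variance", call. = FALSE)
  t <- (a$mean - b$mean) / se
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p,
       group_a = a[c("mean", "sd", "n")],
       group_b = b[c("mean", "sd", "n")],
       box_a = a$box, box_b = b$box)
}

# Tukey box summary: quartiles, whiskers at the most extreme data within
# 1.5 IQR of the box, outliers beyond the whiskers
box_summary <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(v[v >= q[1] - 1.5 * iqr])
  hi <- max(v[v <= q[3] + 1.5 * iqr])
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = lo, whisker_high = hi,
       outliers = v[v < lo | v > hi])
}

#' Read / write a screen table
#'
#' Tab- or comma-separated per-strain tables with the screen's column
#' conventions: `strain` (systematic name), replicate columns `rep_*` or
#' a final `pct_g1`, optional `fsc_mean`, external `size_fl` (haploid
#' median cell volume) and `fitness` (higher = reduced fitness, wild-type
#' like = 1; stored as-is, never inverted), plus any classification
#' columns.
#'
#' @param table Screen data frame.
#' @param path File path; extension `.tsv` selects tab separation.
#' @return `read_screen_table` returns a data frame;
#'   `write_screen_table` returns `path` invisibly.
#' @export
write_screen_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_screen_table
#' @export
read_screen_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
}
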