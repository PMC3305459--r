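# flowG1

Cell-cycle phase deconvolution and G1 screening from DNA-content flow
cytometry, in base R.

In budding yeast, commitment to division (START) happens in G1, and the
fraction of cells in G1 at steady state is a sensitive readout of how
long G1 lasts. `flowG1` implements the full analysis path used by
genome-scale cell-cycle screens built on this idea:

1. **Simulate** list-mode DNA-content samples, whole deletion screens,
   elutriation growth courses and cell-volume distributions with known
   ground truth (`simulate_events()`, `simulate_screen()`,
   `simulate_elutriation()`, `simulate_size_distribution()`).
2. **Read/write flow data**: a hand-rolled FCS 3.0 writer and reader
   (parameters `FSC-H`, `SSC-H`, `FL1-A`, float32), CSV event tables,
   density-based automatic debris gating (`autogate()`) and channel
   binning (`bin_histogram()`).
3. **Fit the Dean–Jett–Fox model** to 1024-channel DNA histograms:
   Gaussian G1 and G2/M peaks plus an S-phase component formed by
   Gaussian-broadening a non-negative quadratic between the peaks,
   estimated by bounded Levenberg–Marquardt on raw channel counts
   (`fit_dean_jett_fox()`). The screen statistic is
   `%G1 = 100 · area_G1 / (area_G1 + area_G2)` (`percent_g1()`), with
   RMS-residual and %G1-extremity quality control (`qc_filter()`).
4. **Screen statistics**: a wild-type normal reference with ±2-sd
   cutoffs (`fit_reference()`), strict-inequality classification into
   `high_g1` / `low_g1` / `wt_like` (`classify_strain()`,
   `classify_screen()`), replicate aggregation with repeat flags,
   Spearman rank correlations against external size/fitness data, and
   Welch two-sample comparisons from raw data or printed summary
   statistics (`compare_groups()`).
5. **G1 length kinetics** from centrifugal-elutriation time courses:
   birth size (10th percentile of a volume distribution), critical size
   (volume at 50% budded), growth rates under linear and exponential
   models with automatic lag exclusion, and the absolute G1 length
   `G1(min) = (critical − birth)/rate` or `G1(h) = ln(critical/birth)/k`
   (`kinetics_summary()`).

## Worked example

```r
library(flowG1)

# a 10,000-event wild-type-like sample with 34% true G1 and 9% debris
ev  <- simulate_events(wt_population_spec(pct_g1 = 34, f_debris = 0.09,
                                          seed = 42))
res <- analyze_sample(ev)   # autogate -> bin -> fit -> QC
res$gate
#> Autogate: retained 9077 / 10000 events (90.8%)
res$fit
#> Dean-Jett-Fox fit
#>   G1: mu 300.3, CV 0.051, area 2438
#>   G2/M: mu 598.7, CV 0.051, area 4840
#>   S: area 1791
#>   %G1 = 33.50, RMS = 4.21, converged: TRUE (n = 9077)
res$qc
#> QC: passed

# classify against a wild-type reference
ref <- fit_reference(c(28.4, 31.2, 33.9, 30.1, 25.8, 36.0))
ref
#> Wild-type %G1 reference: 30.90 +/- 3.69 (n = 6)
#>   2-sd cutoffs: Low G1 < 23.52, High G1 > 38.28
classify_strain(res$fit$pct_g1, ref)
#> [1] "wt_like"

# absolute G1 length from elutriation kinetics
dist <- simulate_size_distribution("lognormal",
                                   list(p10 = 42.12, sdlog = 0.3),
                                   n = 2e5, bin_width = 0.5, seed = 21)
tc   <- simulate_elutriation(growth_spec(birth_size = 42.12,
                                         critical_size = 61.53,
                                         rate_linear = 0.1, noise_sd = 0))
kinetics_summary(dist, tc)
#> G1 kinetics summary
#>   birth size    42.11 fl
#>   critical size 61.49 fl
#>   growth rate   0.1000 fl/min (linear), k = 0.1034 /h (exp)
#>   G1 length     193.8 min (linear), 3.661 h (exponential)
```

A command-line wrapper over the same operations ships in
`inst/scripts/flowg1-cli.R` (subcommands `simulate`, `gate`, `bin`,
`fit`, `classify`, `correlate`, `kinetics`; run it without arguments for
usage).

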