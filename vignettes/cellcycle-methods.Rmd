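---
title: "Methods: DNA-content deconvolution, screen statistics and G1 kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-content deconvolution, screen statistics and G1 kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowG1)
```

This vignette documents the statistical model, the default parameters
and the numerical choices behind every estimator in `flowG1`, and states
explicitly where the package had to make a judgement call.

## 1. The measurement being modelled

A DNA-stained asynchronous budding-yeast culture measured on a linear
1024-channel flow cytometer produces a univariate fluorescence histogram
with two peaks: unreplicated (1C, G1) cells and fully replicated (2C,
G2/M) cells, connected by a shelf of S-phase cells with intermediate DNA
content. The fraction of cells in G1 reflects the relative duration of
G1 in the cycle, so a genome-wide comparison of %G1 across deletion
strains ranks genes by their effect on G1 length.

## 2. Dean–Jett–Fox deconvolution (`fit_dean_jett_fox`)

The expected count in channel $x$ is modelled as

$$
M(x) = A_{G1}\, N(x;\mu_1, cv_1\mu_1) + A_{G2}\, N(x;\mu_2, cv_2\mu_2)
     + \int_{\mu_1}^{\mu_2} q(u)\, N(x; u, \sigma(u))\, du ,
$$

where the S-phase density of DNA content $q$ is a quadratic in the
normalised position $z = (u-\mu_1)/(\mu_2-\mu_1)$ and the broadening
$\sigma(u)$ interpolates linearly between the two peak standard
deviations. The fit is "unconstrained" in the sense that $\mu_2$ is a
free parameter rather than being pinned at $2\mu_1$, and both CVs are
free; this accommodates staining nonlinearity and aneuploid-like
profiles.

Numerical choices:

* **Parameterisation.** The optimiser works on
  $(\mu_1, s, cv_1, cv_2, A_{G1}, A_{G2}, v_0, v_{1/2}, v_1)$ with
  $\mu_2 = s\mu_1$. Bounding the separation $s \in [1.3, 3]$ (default
  `min_sep = 1.3`) prevents the two peak labels from swapping; bounding
  $cv \in [0.005, 0.3]$ keeps the Gaussians non-degenerate.
* **Non-negative S density.** $q$ is parameterised by its values at
  $z = 0, 1/2, 1$, each bounded below by zero, and is additionally
  clamped at zero pointwise (`pmax(q, 0)`) because a non-negative
  quadratic through three non-negative anchors can still dip below zero
  between them. The S integral is discretised at `n_s = 48` midpoints,
  enough that discretisation error is far below Poisson noise at
  10,000 events.
* **Optimiser.** Bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`) on raw channel counts (unweighted least
  squares), up to 200 iterations. The per-iteration residual trace is
  stored and is non-increasing; a stalled run reports
  `converged = FALSE` rather than an error.
* **Initialisation.** $\mu_1$ starts at the smoothed global mode.
  Because G2/M often dominates (at 31% G1 the 2C peak is the taller
  one), a partner mode is searched both at 1.5–2.5× the mode and at
  0.4–0.67× the mode before defaulting to $\mu_2 = 2\mu_1$. CVs start
  from the full width at half maximum.
* **Reported areas.** Component areas are each component's mass over
  the fitted channel range, not the raw Gaussian amplitude parameters.
  A component pushed beyond the observed channels has zero in-range
  gradient (it is unidentifiable), and counting its parameter mass
  would corrupt %G1; evaluating mass in-range makes single-peak
  histograms report %G1 near 100 or 0 as they should, while two-peak
  fits are unchanged to well under 0.1%.

**The statistic.** `percent_g1()` is
$100\,A_{G1}/(A_{G1}+A_{G2})$: the S-phase area is excluded from the
denominator by definition, which makes the statistic robust to how the
flat S shelf trades off against the peak tails.

**Quality control.** `qc_filter()` excludes fits with RMS residual
above 25 raw counts, %G1 below 5 or above 95 (extremes almost always
indicate a broken fit rather than biology), non-convergence, and —
when the histogram is supplied — a `complex_profile` flag for a
prominent secondary mode outside both fitted peaks (e.g. cell-separation
mutants with 4C clumps). The RMS scale of raw counts at 10,000 gated
events matches the scale on which the threshold of 25 was calibrated;
if you gate to a very different event count, rescale `rms_max`
accordingly (it is an explicit argument, not a constant).

## 3. Automatic debris gating (`autogate`)

Events are gated on the (FSC, FL) plane. A 2-D kernel density
(`MASS::kde2d`, 128×128 grid, normal-reference bandwidth with a robust
fallback) is thresholded at 2% of its peak (`threshold_frac = 0.02`);
connected components of the super-threshold region are labelled with
`EBImage::bwlabel`. A component is called debris and removed when its
density-weighted centroid is low in *both* forward scatter
(< `fsc_floor = 50`) and fluorescence (< `fl_floor = 150`) — debris is
small *and* sub-1C; cells are neither. Sub-threshold events are
assigned to the nearest retained component by breadth-first label
propagation, so the gate has no holes, and gating is idempotent. If the
*modal* component is itself debris the sample is rejected as degenerate
rather than silently returning a debris-dominated "gate". On synthetic
samples with 9% debris the gate retains ≈91% of events; on debris-free
samples it retains ≥99%.

## 4. Screen statistics

* `fit_reference()` fits a normal distribution to wild-type %G1 values
  (sample mean and n−1 sd) and sets cutoffs at mean ± 2 sd. With mean
  31.17 and sd 5.20 the cutoffs are 20.77 and 41.57.
* `classify_strain()` uses strict inequalities: a value exactly at a
  cutoff stays `wt_like`. Under a pure null this flags
  $2\Phi(-2) \approx 4.55\%$ of strains, which the test suite verifies.
* `finalize_replicates()` averages QC-passing replicates (mean by
  default; median available via `agg = "median"` for outlier-heavy
  strains) and raises `repeat_flag` when any replicate falls outside
  the cutoffs but fewer than `min_repeats = 2` replicates exist —
  out-of-range measurements require confirmation before a call.
* `spearman()`/`correlate_screen()` use rank correlation (average ranks
  for ties) because %G1, cell size and fitness are monotone-related at
  best; Spearman is invariant to any monotone rescaling of either axis.
* `compare_groups()` implements the Welch unequal-variance t test with
  the Welch–Satterthwaite degrees of freedom, accepting either raw
  values or printed `c(mean, sd, n)` summaries so published group
  statistics can be compared directly, and returns Tukey box-plot
  summaries (whiskers at the most extreme datum within 1.5 IQR).

## 5. G1 length from elutriation kinetics

Newborn daughter cells isolated by centrifugal elutriation grow until
they pass the critical size at START, then bud. Sampling the culture
every 20 minutes for mean volume (Coulter-type channelyzer) and percent
budded gives everything needed for an absolute G1 duration:

* **Birth size** (`birth_size`): the 10th percentile of the
  asynchronous volume distribution — the maximum size of the smallest
  10% of cells — interpolated linearly within the containing bin.
* **Critical size** (`critical_size`): ordinary least squares of
  percent budded against mean volume over the rising portion (budded %
  in [10, 90] by default), inverted at 50%. A near-step response falls
  back to interpolation between the bracketing observations.
* **Growth rate**: the slope of volume vs time (fl/min, linear model)
  or of ln(volume) vs time in hours (k, h⁻¹, exponential model).
  Cultures need time to recover from elutriation, so an initial lag is
  excluded automatically: the smallest initial run of points whose
  removal lifts the straight-line r² to `r2_threshold = 0.95` (the
  r²-maximising run if none reaches it), always keeping ≥ 3 points,
  with a manual `lag_points` override. On noiseless data a stricter
  threshold (e.g. 0.9999) excludes a flat lag exactly.
* **G1 length**: `(critical − birth)/rate` minutes under linear
  growth, `ln(critical/birth)/k` hours under exponential growth. The
  data resolution of typical courses cannot distinguish the two growth
  models, so both are computed and neither is endorsed; the exponential
  form is invariant under rescaling both sizes, the linear form scales
  linearly with sizes at a fixed rate.

## 6. What the synthetic generator does and does not emulate

`simulate_events()` draws phases from a multinomial, gives S-phase
cells a DNA content uniform between the peaks (a *flat* S-phase dwell —
real replication kinetics are not flat, but the DJF quadratic absorbs
smooth deviations), blurs with a CV interpolated between the peaks, and
adds an exponential-tailed sub-1C debris cluster at low forward
scatter. Forward scatter of intact cells scales with DNA content plus
lognormal noise, making FSC a usable size proxy for the gate. It does
*not* emulate doublets/aggregates beyond 2C, time-drift in staining, or
channel saturation other than clipping at channel 1023.

Problem sizes used throughout (10,000 events/sample, 1024 channels,
4,342-strain screens, 20-minute sampling) are the package's own test
scale chosen to match typical bench acquisition; every one of them is a
parameter, not a constant.

```{r example}
ev <- simulate_events(wt_population_spec(pct_g1 = 31.17, seed = 1))
res <- analyze_sample(ev)
res$fit
res$qc
```
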