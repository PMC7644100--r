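---
title: "Trends and scaling in stride-interval dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trends and scaling in stride-interval dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridetrends)
```

## The problem

During treadmill walking, stride time (ST, seconds), stride length (SL,
meters) and stride speed (SS = SL/ST, m/s) fluctuate from one stride to the
next. For decades the persistence found in these series by detrended
fluctuation analysis (DFA) has been attributed to long-range correlated
noise. The alternative view implemented here is that each series is the
superposition of a *piecewise-linear trend* — a sequence of ramps lasting
tens of strides — and small-scale fluctuations that are, if anything,
slightly anti-persistent. Whether apparent persistence comes from the noise
or from the trends matters: trends reflect how the walker steers ST and SL
jointly to hold speed at the belt speed, while the residuals reflect
stride-to-stride motor variability.

The package provides the full chain: explicit trend estimation, trend
characterisation, scaling estimation of trends and residuals, surrogate
and composite null models, and a trend-based speed-control statistic — all
exercisable end to end on synthetic data with known ground truth.

## Trend model: additive piecewise-linear MARS

`fit_mars()` fits

$$f(x) = \beta_0 + \sum_{m=1}^{M} \beta_m h_m(x),$$

where each basis function is one member of a *reflected pair* of linear
splines $\max(0, x - t)$ and $\max(0, t - x)$ with a knot $t$ placed at an
observed abscissa (here, a stride index). The forward pass greedily adds
the pair giving the largest drop in the residual sum of squares, with all
coefficients re-estimated by least squares at each step; it stops when the
relative improvement falls below `stop_threshold` (default 0.001, as a
fraction of the total sum of squares) or when `max_terms` (default 21
basis functions) is reached. The backward pass deletes one basis function
at a time — always the one whose removal raises the residual sum of
squares least — and returns the model in the deletion sequence minimizing
generalized cross-validation,

$$\mathrm{GCV}(\lambda) = \frac{\sum_i \left(y_i - \hat f_\lambda(x_i)\right)^2}{\left(1 - M(\lambda)/N\right)^2},
\qquad M(\lambda) = r + cK,$$

with $r$ the number of linearly independent basis functions, $K$ the
number of knots, and knot penalty $c = 2$ (`gcv_penalty_c`), the customary
value for additive models. The model is additive with interaction order 1:
no products of hinge functions are formed.

Numerical choices:

* Candidate knots are the interior abscissas only; a boundary knot
  duplicates the global line and creates singular designs.
* After the first pair, every additional reflected pair is partly
  collinear with the existing basis (any pair spans the global line), so
  candidates are accepted when they *increase the design rank*, not when
  they keep it full; least-squares fits use the rank-revealing QR of
  `lm.fit`, with redundant coefficients set to zero.
* Ties in the SSE reduction are broken toward the smaller knot, for
  determinism.
* A retained basis function whose coefficient is below
  $10^{-12}\,\mathrm{sd}(y)$ is dropped.

## Trend segments, durations and slopes

`extract_segments()` cuts the fitted trend at its knots. Segments tile the
trial: a knot index belongs to the segment on its left. The *normalized
duration* of a segment is the sum of the parameter's values over the
segment's strides divided by the trial mean — effectively the segment
length in strides, exactly so for a constant series. The *normalized
slope* is the trend change over the segment divided by (trial mean ×
normalized duration). Durations are summarised by a maximum-likelihood
exponential fit (`fit_exponential()`, rate $\hat\lambda = 1/\bar x$) and
slopes by a maximum-likelihood Cauchy fit (`fit_cauchy()`); both report a
Kolmogorov–Smirnov goodness-of-fit p-value by default. An Anderson–Darling
alternative (`gof = "ad"`) uses the one-sample AD statistic with a
parametric-bootstrap p-value, implemented in the package because no
installed library offers the test against an arbitrary fitted CDF; the two
tests can genuinely disagree on heavy-tailed data, which is why both are
exposed.

`small_slope_sections()` selects segments with normalized duration above
40 and |normalized slope| below 0.001 (both configurable) and estimates
the madogram exponent of the raw series over each: on nearly flat
sections the exponent reflects the residual fluctuations, not the trend.

## Scaling estimators

`dfa(y, order)` integrates the mean-centered series (Eq. profile
$Y_t = \sum_{i\le t}(y_i - \bar y)$), splits the profile into
non-overlapping boxes, removes an order-$n$ polynomial per box, and
reports the slope $\alpha$ of $\log F(n)$ vs $\log n$, where $F(n)$ is the
root-mean-square residual over all covered points. Boxes run forward from
the first sample; a trailing remainder is discarded, matching the single
sum in the fluctuation-function definition. The default box grid is
log-spaced from $2(n_\mathrm{order}+1)$ to $N/4$ (for DFA1: 4 to $N/4$,
the convention of the widely used C implementation), with at least 8 grid
points where the range allows; the slope is fitted over the whole grid.
Natural logs are used (the slope is base-invariant).

`madogram_alpha(path)` estimates the fractal dimension of a *path* from
its order-1 power variations at lags 1 and 2,
$\hat D = 2 - \left(\log \hat V(2) - \log \hat V(1)\right)/\log 2$ with
$\hat V(\ell) = \frac{1}{2(N-\ell)}\sum_i |Y_{i+\ell} - Y_i|$, and returns
$\alpha = 2 - \hat D$. A straight line gives $\alpha = 1$ exactly.

Convention: DFA applies to noise-like series (it integrates internally);
the madogram applies to paths. `estimate_alpha(series, method)` therefore
cumulatively sums the mean-centered series before calling the madogram,
treating the sum as the fractional-Brownian-motion-like path whose Hurst
exponent equals the series' scaling exponent. In `fbm_window_study()`,
which operates on simulated FBM paths directly, DFA is applied to
within-window increments and the madogram to the within-window path. This
pairing is the only one under which both estimator families report the
same exponent scale, and it reproduces the known finite-size behaviour:
on windows of 40 samples DFA1 overestimates ($\approx 0.53$ for
$H = 0.40$, $\approx 0.82$ for $H = 0.75$), converging to
$\approx 0.43$ and $\approx 0.76$ at length 260, while the madogram is
nearly unbiased ($\approx 0.41$ and $\approx 0.75$) already at 40
samples. Constant inputs raise an error rather than returning NaN, so
degenerate series fail loudly inside pipelines.

## Fractional Brownian motion generator

`generate_fgn()` simulates exact fractional Gaussian noise by circulant
embedding (Davies–Harte) of the fGn autocovariance
$\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})$, falling back
to the Hosking (Durbin–Levinson) recursion for very short series or if an
embedding eigenvalue is negative. The covariance is exact — no wavelet or
spectral approximation — so generator bias cannot masquerade as estimator
bias in the finite-size studies. `generate_fbm()` cumulatively sums fGn;
paths start at 0.

## Synthetic gait trials

`generate_gait_trial()` emulates a 5-minute treadmill trial:

* **Knots** shared between ST and SL (their trends are strongly coupled
  and their duration distributions indistinguishable), with segment
  lengths drawn from an exponential distribution with rate
  `duration_rate` (default 0.043 per stride, mean ≈ 23 strides), rounded
  to at least 2 strides — a 1-stride ramp has no defined slope.
* **Slopes** drawn from Cauchy distributions (defaults: scale
  $1.2\times10^{-3}$ for ST, $1.5\times10^{-3}$ for SL; locations
  $8\times10^{-4}$ and $6\times10^{-4}$), truncated at ±20 scale units —
  the Cauchy has no moments, and untruncated draws occasionally produce
  physically impossible trials. ST and SL slopes are coupled by a
  Gaussian copula whose correlation is set to
  $\sin(\pi\,\rho_\mathrm{trend}/2)$: the requested coupling acts at the
  concordance (Kendall) level, which compensates the attenuation of
  linear correlation by the heavy-tailed margins. With the default
  request of 0.79 the realized trend–trend Pearson correlation averages
  ≈ 0.8 (between-trial SD ≈ 0.2); the achievable ceiling is ≈ 0.94, so
  requests very close to 1 are realized only approximately.
* **Boundedness.** The belt constrains how far the gait parameters can
  wander, so both trends evolve inside a band of ±5% around their means.
  A step that would leave the band has its sign reflected *jointly* for
  ST and SL — preserving both the slope-magnitude distribution and the
  slope coupling — and is clamped at the band edge only as a last
  resort. The band width is a realism compromise: the resulting ST trend
  COV is ≈ 2.5%, the same order as (though somewhat above) treadmill
  observations.
* **Residuals** are independent fGn with Hurst exponent `residual_hurst`
  (default 0.48, the slightly anti-persistent value typical of detrended
  ST/SL), scaled to `residual_cv` (default 1.5% of the mean; reported
  trial COVs of 1.6–1.8% are totals over trend plus noise, so the
  residual-only value is taken at the same order).
* SS is the exact elementwise ratio SL/ST; `mean_sl` is constructed as
  `treadmill_speed * mean_st`.

The generator matches summary statistics only; it is not a biomechanical
model. It does not emulate within-trial non-stationarity of the noise
variance, slope–duration dependence, or any coupling between residuals of
ST and SL (set to zero by construction) — so tests passing on synthetic
trials demonstrate estimator correctness under these conditions, not
fidelity to every property of experimental gait.

### What the pipeline recovers, and what it cannot

With the defaults, end-to-end recovery over 50 trials (seeds fixed in the
test suite) gives: mean madogram exponent of MARS residuals within ±0.05
of the planted 0.48; mean trend correlation within ±0.1 of the requested
0.79; COV of the trend speed below the COV of stride speed in every
trial. The exponential rate fitted to MARS-segment durations, however,
settles near 0.027–0.029 rather than the planted 0.043: GCV-pruned MARS
cannot resolve planted segments shorter than its detection limit (about
ten strides at 1.5% residual CV) and merges them, lengthening the
apparent durations. The bias shrinks with lower noise but does not vanish
(≈ 0.036 at 0.3% CV with a raised term ceiling). This is a property of
estimating a knot process through a penalized changepoint fit, worth
keeping in mind when interpreting duration statistics from real data: the
fitted rate is a lower bound on the rate of the underlying trend process.

## Surrogates and composite ensembles

`phase_randomize()` keeps the amplitude spectrum and replaces the phases
of positive frequencies with iid uniform draws (DC, and the Nyquist bin
for even lengths, are untouched so the output is real with the original
mean). `cross_correlated_surrogates()` adds the *same* uniform phase
field to both series' spectra, preserving each amplitude spectrum and the
cross-spectrum — hence the cross-correlation — exactly. No amplitude
adjustment (AAFT/IAAFT) is performed, so marginal distributions are not
preserved; that is a documented limitation, matching the plain
phase-randomization convention. `composite_ensemble()` adds random
permutations of the residual pool back onto the fixed trend: shuffling
destroys all serial structure in the noise, so composite persistence
(median DFA1/madogram exponents > 0.5 while shuffled residuals alone give
0.5) isolates the trend as the source of apparent long-range correlation.

## Trend speed control

`trend_speed()` is the per-stride ratio of the SL trend to the ST trend,
and `tsc()` is

$$\mathrm{TSC} = \frac{\sum_{i=1}^{N}\left(v^{(\mathrm{trend})}_i - \langle SS\rangle\right)^2}{N\,\langle SS\rangle^2},$$

zero exactly when the trend speed equals the trial-mean stride speed at
every stride. The statistic is implemented without a square root, as
defined; `sqrt = TRUE` gives the RMS variant for convenience since both
normalizations appear in practice. $\langle SS\rangle$ is the measured
trial-mean stride speed, not the nominal belt speed.

## Group statistics

`group_statistics()` delegates to standard tests: Shapiro–Wilk per group,
Kruskal–Wallis with pairwise Wilcoxon (Holm) post hoc comparisons,
one-way ANOVA with Tukey HSD, pairwise two-sample Kolmogorov–Smirnov, and
left-sided t / Wilcoxon signed-rank tests against 0.5 — the
anti-persistence check for scaling exponents. The significance threshold
used throughout is 0.05. Tests whose sample-size preconditions fail are
skipped with a note rather than an error.

## Problem sizes used in the shipped checks

The finite-size FBM benchmark is run at 500 paths of length 260 in the
acceptance script (seconds of compute) and 200 paths in the test suite;
estimator-recovery properties use ensembles of 100–200 paths of length
1024 for the madogram and 50–60 synthetic trials for the pipeline. These
sizes put Monte-Carlo error comfortably below the asserted tolerances
while keeping the default test run fast.

## A worked example

```{r example, eval = FALSE}
trial <- generate_gait_trial(gait_trial_spec(seed = 1))
analysis <- analyze_trial(trial$st, trial$sl, trial$ss)
analysis
plot(analysis$st_model)          # series, trend, knots
segs <- extract_segments(analysis$st_model, trial$st)
fit_exponential(segs$norm_duration)
```

## Known limitations

* The MARS trend is piecewise linear by design; smooth slow modulations
  are approximated by ramps, and knots closer than a few strides are not
  separable (see the duration-rate bias above).
* DFA box-grid settings influence small-sample exponents; the defaults
  reproduce the benchmark medians quoted above, but other conventions
  (bidirectional boxes, restricted fit ranges) will shift values for
  short windows.
* Phase-randomized surrogates preserve only second-order structure;
  comparisons sensitive to marginal shape require amplitude-adjusted
  variants, which this package deliberately omits.
* The madogram's two-lag estimator is robust but uses only the shortest
  scales; crossover detection is out of scope.
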