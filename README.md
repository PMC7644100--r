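# stridetrends

Explicit trend analysis and scaling estimation for stride-to-stride gait
dynamics.

## The problem

Stride time (ST), stride length (SL) and stride speed (SS = SL/ST) of
treadmill walking fluctuate around slowly varying, piecewise-linear trends.
Detrended fluctuation analysis (DFA) applied to the raw series reports
strong persistence (scaling exponent α well above 0.5), which has long been
read as long-range correlated motor noise. If the trends are estimated
explicitly and removed, the picture inverts: the residual fluctuations are
slightly anti-persistent (α ≈ 0.48), and the apparent persistence is a
property of the trends. The trends themselves are not noise — the ratio of
the SL trend to the ST trend (the *trend speed*) tracks the belt speed far
more tightly than stride speed itself does, which is how a walker keeps
speed while letting ST and SL drift together along the constant-speed
manifold.

`stridetrends` is for researchers in gait dynamics and fractal physiology
who want that decomposition end to end:

* **Trend model** — one-dimensional additive piecewise-linear MARS
  (multivariate adaptive regression splines): greedy forward selection of
  reflected hinge pairs max(0, x−t), max(0, t−x), then backward pruning by
  generalized cross-validation, GCV(λ) = RSS / (1 − M(λ)/N)² with
  M(λ) = r + cK and knot penalty c = 2 (`fit_mars()`, an S3 model with
  `predict`, `coef`, `summary`, `plot`, `residuals` methods).
* **Scaling estimators** — DFA of order 1–3 (`dfa()`) and the madogram
  fractal-dimension estimator, α = 2 − D̂₁ with
  D̂₁ = 2 − (log V̂(2) − log V̂(1))/log 2 (`madogram_alpha()`), plus
  windowed sweeps over data-window length (`window_sweep()`,
  `fbm_window_study()`).
* **Trend statistics** — segment extraction, normalized durations and
  slopes, exponential and Cauchy maximum-likelihood fits with KS or
  Anderson–Darling goodness of fit, small-slope section analysis.
* **Null models** — phase-randomized surrogates, cross-correlated
  surrogate pairs sharing one random phase field, and trend +
  shuffled-residual composite ensembles.
* **Speed control** — trend speed, the TSC statistic
  TSC = Σᵢ(vᵢ⁽ᵗʳᵉⁿᵈ⁾ − ⟨SS⟩)² / (N⟨SS⟩²), coefficients of variation, and
  three-level ST–SL correlations (raw / trend / residual).
* **Synthetic data** — exact fractional Gaussian noise and fractional
  Brownian motion (circulant embedding with Hosking fallback) and a
  coupled ST/SL/SS trial generator with ground-truth trends and knots, so
  every stage is testable without experimental recordings.

## Worked example

```r
library(stridetrends)

trial <- generate_gait_trial(gait_trial_spec(seed = 1))
trial
#> Synthetic gait trial: 260 strides, belt 1.25 m/s, 12 trend knot(s)
#>   mean ST 1.111 s, mean SL 1.403 m, mean SS 1.263 m/s

analysis <- analyze_trial(trial$st, trial$sl, trial$ss)
analysis
#> Gait trial analysis (260 strides)
#>   trend knots: ST 7, SL 7
#>   ST alpha(MD): raw 0.96, residual 0.48
#>   SL alpha(MD): raw 0.97, residual 0.50
#>   TSC = 0.0001857; COV: v_trend 1.37%, SS 2.44%, SL 3.82%, ST 3.84%
#>   rho: raw 0.80, trend 0.93, noise 0.00
```

Reading the output: the raw madogram exponents (≈ 0.96) say the series
look strongly persistent, but the MARS residuals sit at ≈ 0.48–0.50 — the
persistence lives in the trends. The trend speed varies far less
(COV 1.37%) than stride speed (2.44%) even though ST and SL individually
wander by almost 4%, and the trends are strongly coupled (ρ_trend = 0.93)
while the residuals are uncorrelated: ST and SL are steered jointly to
hold speed. TSC near zero quantifies how close the trend speed stays to
the mean stride speed.

Pooling trend segments across trials characterises the trend process:

```r
durs <- c()
for (s in 1:10) {
  tr <- generate_gait_trial(gait_trial_spec(seed = s))
  an <- analyze_trial(tr$st, tr$sl, tr$ss, methods = "MD")
  durs <- c(durs, an$segments$ST$norm_duration, an$segments$SL$norm_duration)
}
fit_exponential(durs)
#> Exponential fit: rate = 0.02867 (mean 34.88), n = 149, KS p = 3.84e-05
```

The finite-size estimator benchmark on short fractional Brownian motion:

```r
fbm_window_study(0.40, n_paths = 200, length = 260, k_values = c(40, 260), seed = 5)
#> Windowed scaling-exponent sweep; median alpha by method and window:
#>         40   260
#> DFA1 0.543 0.435
#> MD   0.417 0.406
```

On 40-sample windows DFA1 overestimates H = 0.40 by more than 0.1 while
the madogram is nearly unbiased — the reason the madogram is the preferred
estimator for short gait segments.

## Vignette

`vignettes/gait-trend-analysis.Rmd` documents the model and estimator
conventions, the synthetic-trial generator and what it does and does not
emulate, numerical choices, and known limitations (including the downward
bias of trend-duration rates recovered through a pruned changepoint fit).
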