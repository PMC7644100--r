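test_that("phase randomization preserves the amplitude spectrum and mean", {
  for (s in 1:5) {
    y <- generate_fgn(128 + s, hurst = 0.6, seed = s)[1, ]
    sur <- phase_randomize(y, seed = 10 + s)
    expect_lt(max(abs(Mod(fft(sur)) - Mod(fft(y)))) / max(Mod(fft(y))), 1e-10)
    expect_equal(mean(sur), mean(y), tolerance = 1e-10)
  }
  expect_error(phase_randomize(rnorm(5)), "length")
})

test_that("a pure cosine surrogate is a phase-shifted cosine", {
  t <- 0:63
  y <- cos(2 * pi * 4 * t / 64)
  sur <- phase_randomize(y, seed = 3)
  # single spectral line: same amplitude and frequency, shifted phase
  expect_lt(max(abs(Mod(fft(sur)) - Mod(fft(y)))), 1e-10)
  fit <- lm(sur ~ cos(2 * pi * 4 * t / 64) + sin(2 * pi * 4 * t / 64))
  expect_lt(summary(fit)$sigma, 1e-10)
})

test_that("madogram exponent is invariant under phase randomization of fGn", {
  y <- generate_fgn(512, hurst = 0.75, seed = 8)[1, ]
  a0 <- estimate_alpha(y, "MD")$alpha
  a_sur <- sapply(1:50, function(r) estimate_alpha(phase_randomize(y), "MD")$alpha)
  expect_lt(abs(mean(a_sur) - a0), 0.07)
})

test_that("cross-correlated surrogates share phases and preserve coupling", {
  y <- generate_fgn(256, hurst = 0.6, seed = 12)[1, ]
  cc <- cross_correlated_surrogates(y, y, seed = 1)
  expect_equal(cc$s1, cc$s2)
  expect_error(cross_correlated_surrogates(rnorm(64), rnorm(65)), "equal length")
  # coupled trends: CCS preserves the cross-correlation, IS destroys it
  tr <- generate_gait_trial(gait_trial_spec(seed = 3, residual_cv = 0.002))
  t1 <- tr$true_st_trend; t2 <- tr$true_sl_trend
  rho0 <- cor(t1, t2)
  set.seed(20)
  rho_ccs <- replicate(50, { s <- cross_correlated_surrogates(t1, t2)
                             cor(s$s1, s$s2) })
  rho_is <- replicate(50, cor(phase_randomize(t1), phase_randomize(t2)))
  expect_lt(abs(mean(rho_ccs) - rho0), 0.1)
  expect_lt(abs(mean(rho_is)), 0.25)
})

test_that("composite realizations are trend plus a permutation of residuals", {
  tr <- generate_gait_trial(gait_trial_spec(seed = 5))
  resid <- tr$st$values - tr$true_st_trend
  ce <- composite_ensemble(tr$true_st_trend, resid, n_realizations = 20,
                           seed = 2)
  for (i in c(1, 10, 20))
    expect_equal(sort(ce$realizations[i, ] - tr$true_st_trend), sort(resid))
  # zero residuals: every realization equals the trend; a single linear
  # trend has madogram exponent 1
  lin <- 1 + 0.001 * (1:200)
  ce0 <- composite_ensemble(lin, rep(0, 200), n_realizations = 3, seed = 1)
  expect_true(all(ce0$realizations[1, ] == lin))
  expect_equal(madogram_alpha(lin)$alpha, 1)
})

test_that("shuffled residuals alone are uncorrelated while trend composites are persistent", {
  tr <- generate_gait_trial(gait_trial_spec(seed = 6))
  resid <- tr$st$values - tr$true_st_trend
  ce_noise <- composite_ensemble(rep(0, length(resid)), resid,
                                 n_realizations = 50, seed = 3,
                                 methods = "DFA1")
  med_noise <- median(ce_noise$exponents$alpha, na.rm = TRUE)
  expect_lt(abs(med_noise - 0.5), 0.05)
  ce_comp <- composite_ensemble(tr$true_st_trend, resid,
                                n_realizations = 50, seed = 4,
                                methods = c("DFA1", "MD"))
  meds <- tapply(ce_comp$exponents$alpha, ce_comp$exponents$method, median)
  expect_true(all(meds > 0.5))
})

test_that("surrogate comparison flags identical data as indistinguishable", {
  ys <- lapply(1:4, function(s) generate_fgn(128, 0.6, seed = 30 + s)[1, ])
  res <- surrogate_comparison(ys, statistic = function(y) y,  # identity pool
                              kind = "IS", n_realizations = 5, seed = 1)
  expect_true(all(res$p_values >= 0))
  # statistic computed on the original set compared with itself: p = 1
  p_self <- suppressWarnings(ks.test(unlist(ys), unlist(ys)))$p.value
  expect_equal(p_self, 1)
  # madogram alpha is a linear-process property: IS rarely changes it
  res2 <- surrogate_comparison(ys, statistic = function(y)
    estimate_alpha(y, "MD")$alpha, kind = "IS", n_realizations = 10, seed = 2)
  expect_lte(res2$rejection_fraction, 0.5)
})
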