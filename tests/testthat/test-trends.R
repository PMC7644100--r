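make_segments <- function(model, y) extract_segments(model, y)

test_that("segment extraction tiles the trial and handles no-trend fits", {
  # intercept-only model: empty list, the no-MARS-trend case
  m0 <- fit_mars(1:100, rep(1.1, 100))
  expect_equal(nrow(extract_segments(m0, rep(1.1, 100))), 0)
  # single knot at 100 on a 250-stride series: [1,100] and [100,250]
  x <- 1:250
  y <- 1 + 0.002 * pmax(0, x - 100)
  m <- fit_mars(x, y)
  segs <- extract_segments(m, y)
  expect_equal(segs$start_idx, c(1, 100))
  expect_equal(segs$end_idx, c(100, 250))
  # strides partition [1, N]: owned counts sum to N
  expect_equal(sum(segs$n_strides), 250)
})

test_that("normalized duration and slope follow their definitions", {
  y <- rep(0.8, 100)
  # a non-first segment owns strides start+1 .. end: 23 strides here
  seg <- list(start_idx = 9, end_idx = 32)
  expect_equal(normalized_duration(seg, y, first_segment = FALSE), 23)
  expect_equal(normalized_duration(list(start_idx = 1, end_idx = 23), y), 23)
  # slope: delta 0.01 over mean 1.0 and duration 10 -> 0.001
  seg2 <- list(start_idx = 1, end_idx = 10, delta_y = 0.01)
  expect_equal(normalized_slope(seg2, rep(1, 50)), 0.001)
  seg3 <- list(start_idx = 1, end_idx = 10, delta_y = 0)
  expect_equal(normalized_slope(seg3, rep(1, 50)), 0)
  expect_error(normalized_duration(list(start_idx = 5, end_idx = 4), y,
                                   first_segment = FALSE), "empty")
})

test_that("exponential fit is the closed-form MLE with sane errors", {
  d <- rep(1 / 0.043, 50)
  expect_equal(fit_exponential(d)$rate, 0.043)
  set.seed(4)
  s <- rexp(1500, rate = 0.043)
  f <- fit_exponential(s)
  expect_lt(abs(f$rate - 0.043), 0.005)
  expect_true(f$gof_p >= 0 && f$gof_p <= 1)
  expect_error(fit_exponential(rexp(5, 1)), "at least 10")
  expect_error(fit_exponential(c(rep(1, 20), -1)), "positive")
  # AD alternative returns a valid p-value
  f2 <- fit_exponential(s[1:200], gof = "ad")
  expect_true(f2$gof_p > 0 && f2$gof_p <= 1)
})

test_that("Cauchy fit recovers location and scale", {
  set.seed(6)
  s <- rcauchy(1600, location = 8e-4, scale = 1.2e-3)
  f <- fit_cauchy(s)
  expect_lt(abs(f$location - 8e-4), 3e-4)
  expect_lt(abs(f$scale - 1.2e-3), 2e-4)
  grid <- c(-(5:1), 0, 1:5) * 1e-3
  expect_lt(abs(fit_cauchy(grid)$location), 1e-4)
  expect_error(fit_cauchy(rep(1, 20)), "degenerate")
  expect_error(fit_cauchy(rcauchy(5)), "at least 10")
})

test_that("generator duration and slope statistics are recovered from true segments", {
  durs <- c(); slopes <- c()
  for (i in 1:40) {
    tr <- generate_gait_trial(gait_trial_spec(seed = 800 + i))
    bounds <- c(1, tr$true_knots, length(tr$st$values))
    tv <- tr$true_st_trend
    for (j in seq_len(length(bounds) - 1)) {
      seg <- list(start_idx = bounds[j], end_idx = bounds[j + 1],
                  delta_y = tv[bounds[j + 1]] - tv[bounds[j]])
      durs <- c(durs, normalized_duration(seg, tr$st$values,
                                          first_segment = j == 1))
      slopes <- c(slopes, normalized_slope(seg, tr$st$values,
                                           first_segment = j == 1))
    }
  }
  fe <- fit_exponential(durs)
  expect_lt(abs(fe$rate - 0.043), 0.008)
  fc <- fit_cauchy(slopes)
  expect_lt(abs(fc$scale - 1.2e-3) / 1.2e-3, 0.30)
})

test_that("small-slope sections expose the residual scaling exponent", {
  # planted 60-stride zero-slope plateau with fGn residuals (H = 0.48)
  alphas <- sapply(1:60, function(s) {
    mu <- 1.12
    n <- 260
    trend <- c(mu * (1 + 0.0012 * (100:1) / 100),   # descending approach
               rep(mu, 60),                          # flat plateau
               mu * (1 + 0.0015 * (1:100) / 100))
    e <- generate_fgn(n, 0.48, seed = 900 + s)[1, ]
    y <- trend + e / sd(e) * 0.015 * mu
    segs <- data.frame(start_idx = c(1, 101, 161), end_idx = c(100, 160, 260),
                       norm_duration = c(100, 60, 100),
                       norm_slope = c(-1.2e-3, 0, 1.5e-3))
    out <- small_slope_sections(segs, y)
    out$alpha_md
  })
  expect_equal(length(alphas), 60)  # exactly the plateau qualifies each time
  expect_lt(abs(median(alphas) - 0.48), 0.08)
  # no qualifying segments -> empty
  segs <- data.frame(start_idx = 1, end_idx = 50, norm_duration = 50,
                     norm_slope = 0.5)
  expect_equal(nrow(small_slope_sections(segs, rnorm(50) + 10)), 0)
  expect_error(small_slope_sections(segs, rnorm(50), min_norm_len = -1),
               "positive")
})

test_that("segment tables aggregate across trials", {
  tr <- generate_gait_trial(gait_trial_spec(seed = 15))
  m <- fit_mars(1:260, tr$st$values)
  s <- extract_segments(m, tr$st$values)
  tab <- segments_table(list(A = s, B = s), parameter = "ST")
  expect_equal(nrow(tab), 2 * nrow(s))
  expect_true(all(c("trial_id", "parameter", "norm_duration", "norm_slope")
                  %in% names(tab)))
})
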