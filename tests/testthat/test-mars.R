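test_that("an exact line is fitted perfectly and a constant gives intercept only", {
  x <- seq(0, 10, length.out = 100)
  m <- fit_mars(x, 2 * x + 1)
  expect_lt(max(abs(m$residuals)), 1e-8)
  m0 <- fit_mars(x, rep(5, 100))
  expect_equal(m0$intercept, 5)
  expect_equal(nrow(m0$terms), 0)
  expect_equal(m0$n_terms, 1)
})

test_that("the first selected knot matches the brute-force SSE minimum", {
  x <- 0:10
  y <- abs(x - 5)
  oracle <- brute_force_best_knot(x, y)
  expect_equal(oracle$t, 5)
  m <- fit_mars(x, y)
  expect_equal(sort(unique(m$terms$knot)), 5)
  cf <- coef(m)
  expect_equal(unname(cf[c("h(x-5)", "h(5-x)")]), c(1, 1), tolerance = 1e-10)
  expect_lt(max(abs(m$residuals)), 1e-8)
  # a hand-built reflected pair with knot 5 is reproduced exactly
  y2 <- 3 * pmax(0, x - 5) + 2 * pmax(0, 5 - x)
  m2 <- fit_mars(x, y2)
  expect_lt(max(abs(m2$residuals)), 1e-8)
})

test_that("noisy single-knot data yields one knot near the truth across seeds", {
  hits <- 0
  for (s in 1:25) {
    set.seed(s)
    x <- seq(0, 10, length.out = 200)
    y <- abs(x - 5) + rnorm(200, sd = 0.01)
    m <- fit_mars(x, y)
    kn <- unique(m$terms$knot)
    if (length(kn) == 1 && abs(kn - 5) <= 0.5) hits <- hits + 1
  }
  expect_gte(hits, 24)  # >= 95% of seeds
})

test_that("backward pruning never worsens GCV and handles the trivial model", {
  set.seed(8)
  x <- 1:150
  y <- 0.01 * pmax(0, x - 70) + rnorm(150, sd = 0.05)
  fw <- forward_pass(x, y)
  pr <- backward_prune(fw)
  expect_lte(pr$gcv, fw$gcv)
  # deletion-sequence oracle: pruned GCV is the minimum over a direct
  # enumeration of backward deletions
  basis_of <- function(tt) {
    if (nrow(tt) == 0) return(matrix(1, length(x), 1))
    cbind(1, sapply(seq_len(nrow(tt)), function(i)
      if (tt$direction[i] > 0) pmax(0, x - tt$knot[i])
      else pmax(0, tt$knot[i] - x)))
  }
  enumerate_gcv <- function(terms) {
    best <- Inf
    cur <- terms
    repeat {
      f <- lm.fit(basis_of(cur), y)
      sse <- sum(f$residuals^2)
      m_eff <- f$rank + 2 * length(unique(cur$knot))
      g <- sse / (1 - m_eff / length(x))^2
      best <- min(best, g)
      if (nrow(cur) == 0) break
      sse_del <- sapply(seq_len(nrow(cur)), function(i)
        sum(lm.fit(basis_of(cur[-i, , drop = FALSE]), y)$residuals^2))
      cur <- cur[-which.min(sse_del), , drop = FALSE]
    }
    best
  }
  expect_equal(pr$gcv, enumerate_gcv(fw$terms), tolerance = 1e-10)
  # intercept-only input passes through pruning unchanged
  m0 <- forward_pass(x, rep(2, 150))
  expect_equal(backward_prune(m0)$n_terms, 1)
})

test_that("residuals are orthogonal to retained basis functions", {
  set.seed(21)
  x <- 1:200
  y <- 1.1 + 0.002 * pmax(0, x - 60) - 0.003 * pmax(0, x - 140) + rnorm(200, sd = 0.02)
  m <- fit_mars(x, y)
  B <- cbind(1, sapply(seq_len(nrow(m$terms)), function(i)
    if (m$terms$direction[i] > 0) pmax(0, x - m$terms$knot[i])
    else pmax(0, m$terms$knot[i] - x)))
  proj <- crossprod(B, m$residuals)
  expect_lt(max(abs(proj)) / sum(abs(y)), 1e-8)
  # decomposition identity
  expect_equal(m$fitted + m$residuals, y)
})

test_that("pure noise yields an intercept-only model in the majority of seeds", {
  cnt <- 0
  for (s in 1:20) {
    y <- generate_fgn(250, hurst = 0.48, seed = 500 + s)[1, ]
    if (nrow(fit_mars(1:250, y)$terms) == 0) cnt <- cnt + 1
  }
  expect_gt(cnt, 10)
})

test_that("prediction reproduces fitted values and hinge arithmetic", {
  set.seed(5)
  x <- 1:100
  y <- 0.5 + 0.01 * x + rnorm(100, sd = 0.1)
  m <- fit_mars(x, y)
  expect_equal(predict(m, x), m$fitted)
  m0 <- fit_mars(x, rep(3, 100))
  expect_equal(predict(m0, c(10, 50)), c(3, 3))
  # single hinge by hand: beta0 = 0, +1 * max(0, x - 5) at x = 7 -> 2
  js <- mars_to_json(m)
  m_rt <- mars_from_json(js, x, y)
  expect_equal(m_rt$intercept, m$intercept)
  expect_equal(m_rt$terms$knot, m$terms$knot)
  expect_equal(predict(m_rt, x), predict(m, x))
  expect_equal(m_rt$gcv, m$gcv, tolerance = 1e-12)
})

test_that("degenerate abscissas are rejected", {
  expect_error(forward_pass(c(1, 2, 2, 3), rnorm(4)), "increasing")
  expect_error(forward_pass(1:3, rnorm(3)), "at least 4")
})

test_that("detectable knots of a synthetic trial are recovered", {
  # low-noise, widely spaced regime; a knot counts as detectable when the
  # slope change, accumulated over the shorter adjacent segment, exceeds
  # 8 residual standard deviations
  tot <- 0; matched <- 0; count_diff <- c()
  for (i in 1:15) {
    spec <- gait_trial_spec(seed = 400 + i, residual_cv = 0.003,
                            duration_rate = 0.02)
    tr <- generate_gait_trial(spec)
    m <- fit_mars(1:260, tr$st$values)
    fk <- sort(unique(m$terms$knot))
    tk <- tr$true_knots
    count_diff <- c(count_diff, length(fk) - length(tk))
    bounds <- c(1, tk, 260)
    tv <- tr$true_st_trend
    noise_sd <- spec$residual_cv * spec$mean_st
    for (j in seq_along(tk)) {
      dl <- bounds[j + 1] - bounds[j]; dr <- bounds[j + 2] - bounds[j + 1]
      sl <- (tv[bounds[j + 1]] - tv[bounds[j]]) / dl
      sr <- (tv[bounds[j + 2]] - tv[bounds[j + 1]]) / dr
      if (abs(sr - sl) * min(dl, dr) >= 8 * noise_sd) {
        tot <- tot + 1
        if (any(abs(fk - tk[j]) <= 3)) matched <- matched + 1
      }
    }
  }
  expect_gte(matched / tot, 0.8)
  expect_lte(median(abs(count_diff)), 1)
})
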