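# Naive reference implementations used as independent oracles.
# Deliberately loop-based and unvectorized; kept separate from the package.

# DFA: explicit per-box polynomial fits on the integrated profile
naive_dfa_alpha <- function(y, order, window_sizes) {
  prof <- cumsum(y - mean(y))
  n <- length(prof)
  fl <- numeric(length(window_sizes))
  for (wi in seq_along(window_sizes)) {
    w <- window_sizes[wi]
    nb <- floor(n / w)
    ss <- 0
    for (b in seq_len(nb)) {
      idx <- ((b - 1) * w + 1):(b * w)
      t_loc <- seq_len(w)
      fit <- lm(prof[idx] ~ poly(t_loc, degree = order, raw = TRUE))
      ss <- ss + sum(resid(fit)^2)
    }
    fl[wi] <- sqrt(ss / (nb * w))
  }
  unname(coef(lm(log(fl) ~ log(window_sizes)))[2])
}

# madogram: direct double-sum power variations
naive_madogram_alpha <- function(path) {
  n <- length(path)
  v <- function(l) {
    s <- 0
    for (i in 1:(n - l)) s <- s + abs(path[i + l] - path[i])
    s / (2 * (n - l))
  }
  d <- 2 - (log(v(2)) - log(v(1))) / log(2)
  2 - d
}

# brute-force best single reflected pair by SSE (for MARS knot checks)
brute_force_best_knot <- function(x, y) {
  best <- NULL
  for (t in x[-c(1, length(x))]) {
    X <- cbind(1, pmax(0, x - t), pmax(0, t - x))
    sse <- sum(lm.fit(X, y)$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12) best <- list(t = t, sse = sse)
  }
  best
}

# lag-l increment variance structure function slope (FBM self-affinity)
structure_slope <- function(path, lags) {
  v <- sapply(lags, function(l) {
    d <- path[(1 + l):length(path)] - path[1:(length(path) - l)]
    mean(d^2)
  })
  unname(coef(lm(log(v) ~ log(lags)))[2])
}
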