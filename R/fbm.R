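#' Autocovariance of fractional Gaussian noise
#'
#' Autocovariance function of unit-variance fractional Gaussian noise (fGn),
#' the stationary increment process of fractional Brownian motion with Hurst
#' exponent \code{hurst}.
#'
#' @param k integer vector of lags (k >= 0).
#' @param hurst Hurst exponent in (0, 1].
#' @return numeric vector of autocovariances at the requested lags.
#' @keywords internal
fgn_autocov <- function(k, hurst) {
  h2 <- 2 * hurst
  0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

## Exact circulant-embedding (Davies-Harte) synthesis of n fGn samples.
## Returns a matrix n_paths x n, or NULL when the embedding is not
## non-negative definite (caller falls back to Hosking).
.fgn_davies_harte <- function(n, hurst, n_paths) {
  g <- fgn_autocov(0:(n - 1), hurst)
  # first row of the 2(n-1) circulant (n >= 2)
  m <- 2 * (n - 1)
  row <- c(g, g[(n - 1):2])
  lam <- Re(stats::fft(row))
  if (any(lam < -1e-8 * max(lam))) return(NULL)
  lam[lam < 0] <- 0
  out <- matrix(0, n_paths, n)
  for (p in seq_len(n_paths)) {
    # complex Gaussian weights with the required Hermitian structure
    z <- complex(length.out = m)
    z[1] <- stats::rnorm(1) * sqrt(m)
    z[n] <- stats::rnorm(1) * sqrt(m)
    a <- stats::rnorm(n - 2)
    b <- stats::rnorm(n - 2)
    z[2:(n - 1)] <- complex(real = a, imaginary = b) * sqrt(m / 2)
    z[m:(n + 1)] <- Conj(z[2:(n - 1)])
    w <- stats::fft(sqrt(lam) * z, inverse = TRUE) / m
    out[p, ] <- Re(w)[1:n]
  }
  out
}

## Hosking's recursion: exact sequential simulation of fGn via the
## Durbin-Levinson algorithm. O(n^2) per path; used only when the circulant
## embedding fails (it does not for hurst <= 1 at the lengths used here).
.fgn_hosking <- function(n, hurst, n_paths) {
  g <- fgn_autocov(0:(n - 1), hurst)
  out <- matrix(0, n_paths, n)
  for (p in seq_len(n_paths)) {
    x <- numeric(n)
    phi <- numeric(n)
    v <- g[1]
    x[1] <- stats::rnorm(1) * sqrt(v)
    for (i in seq_len(n - 1)) {
      phi_new <- numeric(i)
      acc <- g[i + 1]
      if (i > 1) acc <- acc - sum(phi[1:(i - 1)] * g[i:2])
      phi_new[i] <- acc / v
      if (i > 1) {
        phi_new[1:(i - 1)] <- phi[1:(i - 1)] - phi_new[i] * phi[(i - 1):1]
      }
      phi[1:i] <- phi_new
      v <- v * (1 - phi_new[i]^2)
      x[i + 1] <- sum(phi[1:i] * x[i:1]) + stats::rnorm(1) * sqrt(v)
    }
    out[p, ] <- x
  }
  out
}

#' Generate fractional Gaussian noise
#'
#' Simulates paths of unit-variance fractional Gaussian noise with exact
#' covariance, using circulant embedding (Davies-Harte) with a Hosking
#' recursion fallback when the embedding is not non-negative definite.
#'
#' @param n number of samples per path (>= 2).
#' @param hurst Hurst exponent in (0, 1].
#' @param n_paths number of independent paths.
#' @param seed optional integer seed for reproducibility.
#' @return numeric matrix with \code{n_paths} rows and \code{n} columns.
#' @examples
#' x <- generate_fgn(256, hurst = 0.75, seed = 1)
#' @export
generate_fgn <- function(n, hurst, n_paths = 1, seed = NULL) {
  stopifnot(length(n) == 1, length(hurst) == 1)
  if (!is.finite(hurst) || hurst <= 0 || hurst > 1)
    stop("'hurst' must lie in (0, 1]")
  if (!is.finite(n) || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2")
  if (n_paths < 1) stop("'n_paths' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- if (n < 4) NULL else .fgn_davies_harte(n, hurst, n_paths)
  if (is.null(out)) out <- .fgn_hosking(n, hurst, n_paths)
  out
}

#' Generate fractional Brownian motion paths
#'
#' Simulates an ensemble of fractional Brownian motion (FBM) paths by
#' cumulatively summing exact fractional Gaussian noise. Every path starts
#' at zero; increments are stationary with the requested Hurst exponent.
#'
#' @param length number of samples per path (>= 2), including the initial 0.
#' @param hurst Hurst exponent in (0, 1].
#' @param n_paths number of independent paths.
#' @param seed optional integer seed.
#' @return numeric matrix (\code{n_paths} x \code{length}); each row a path
#'   starting at 0.
#' @examples
#' paths <- generate_fbm(260, hurst = 0.40, n_paths = 10, seed = 42)
#' @export
generate_fbm <- function(length, hurst, n_paths = 1, seed = NULL) {
  inc <- generate_fgn(length - 1, hurst, n_paths, seed)
  cbind(0, t(apply(inc, 1, cumsum)))
}

#' First differences of a path
#'
#' Increment (noise) series of a sampled path: the inverse of cumulative
#' summation, so \code{cumsum(fgn_from_fbm(p)) + p[1]} reproduces \code{p}.
#'
#' @param path numeric vector of length >= 2.
#' @return numeric vector of length \code{length(path) - 1}.
#' @export
fgn_from_fbm <- function(path) {
  if (length(path) < 2) stop("'path' must have length >= 2")
  diff(path)
}
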