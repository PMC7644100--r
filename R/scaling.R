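#' Default DFA box-size grid
#'
#' Logarithmically spaced integer box sizes from \code{2 * (order + 1)} to
#' \code{floor(n / 4)} (at least 8 sizes where the range allows), the
#' conventional grid for detrended fluctuation analysis.
#'
#' @param n series length.
#' @param order polynomial detrending order.
#' @return integer vector of box sizes.
#' @export
dfa_window_sizes <- function(n, order = 1) {
  lo <- 2 * (order + 1)
  hi <- floor(n / 4)
  if (hi < lo) stop("series too short for DFA of order ", order)
  n_pts <- max(8, ceiling(log2(hi / lo) * 4))
  ws <- unique(round(exp(seq(log(lo), log(hi), length.out = n_pts))))
  ws[ws >= lo & ws <= hi]
}

#' Detrended fluctuation analysis
#'
#' DFA of order \code{order}: the mean-centered series is integrated, the
#' integrated profile is divided into non-overlapping boxes of each size,
#' an order-\code{order} polynomial is fitted per box, and the fluctuation
#' function F(n) is the root-mean-square deviation from those fits. The
#' scaling exponent alpha is the least-squares slope of log F(n) versus
#' log n.
#'
#' @param y numeric series (noise-like signal, e.g. stride times or fGn).
#' @param order polynomial detrending order (1, 2 or 3).
#' @param window_sizes integer box sizes; defaults to
#'   \code{dfa_window_sizes(length(y), order)}.
#' @return object of class \code{"dfa"}: list with \code{alpha},
#'   \code{order}, \code{window_sizes}, \code{fluctuation}, \code{fit_r2}.
#' @examples
#' r <- dfa(rnorm(1000), order = 1)
#' r$alpha  # ~0.5 for white noise
#' @export
dfa <- function(y, order = 1, window_sizes = NULL) {
  if (order < 1 || order != round(order)) stop("'order' must be a positive integer")
  n <- length(y)
  if (is.null(window_sizes)) window_sizes <- dfa_window_sizes(n, order)
  window_sizes <- sort(unique(as.integer(window_sizes)))
  if (any(window_sizes < order + 2)) stop("window sizes must be >= order + 2")
  if (n < 2 * min(window_sizes)) stop("series too short for requested window sizes")
  if (stats::sd(y) == 0) stop("constant input: scaling exponent undefined")
  prof <- cumsum(y - mean(y))
  fl <- vapply(window_sizes, function(w) {
    nb <- n %/% w
    t_loc <- seq_len(w)
    X <- stats::poly(t_loc, degree = order, raw = TRUE)
    X <- cbind(1, X)
    qrX <- qr(X)
    ss <- 0
    for (b in seq_len(nb)) {
      seg <- prof[((b - 1) * w + 1):(b * w)]
      res <- qr.resid(qrX, seg)
      ss <- ss + sum(res^2)
    }
    sqrt(ss / (nb * w))
  }, numeric(1))
  if (any(fl <= 0)) stop("zero fluctuation: scaling exponent undefined")
  lx <- log(window_sizes); ly <- log(fl)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(alpha = alpha, order = order,
                 window_sizes = window_sizes, fluctuation = fl,
                 fit_r2 = r2),
            class = "dfa")
}

#' @export
print.dfa <- function(x, ...) {
  cat(sprintf("DFA%d scaling exponent: alpha = %.3f (R2 = %.4f)\n",
              x$order, x$alpha, x$fit_r2))
  cat(sprintf("  box sizes: %d values in [%d, %d]\n",
              length(x$window_sizes), min(x$window_sizes), max(x$window_sizes)))
  invisible(x)
}

#' Madogram scaling-exponent estimator
#'
#' Estimates the fractal dimension of a sampled path from its order-1 power
#' variations at lags 1 and 2,
#' \deqn{\hat D = 2 - (\log \hat V(2) - \log \hat V(1)) / \log 2,}
#' with \eqn{\hat V(l) = \frac{1}{2(N-l)} \sum_i |Y_{i+l} - Y_i|}, and
#' returns the scaling exponent \eqn{\alpha = 2 - \hat D}.
#'
#' The input must be the \emph{path} (an FBM-like, integrated signal). For a
#' noise-like series use \code{\link{estimate_alpha}} with
#' \code{method = "MD"}, which integrates first.
#'
#' @param path numeric vector of length >= 3.
#' @return list with \code{alpha}, \code{fractal_dim}, \code{p}, \code{v1},
#'   \code{v2}.
#' @examples
#' madogram_alpha(3 * (1:100))$alpha  # a straight line has alpha = 1
#' @export
madogram_alpha <- function(path) {
  n <- length(path)
  if (n < 3) stop("'path' must have length >= 3")
  v1 <- sum(abs(path[-1] - path[-n])) / (2 * (n - 1))
  v2 <- sum(abs(path[-(1:2)] - path[-((n - 1):n)])) / (2 * (n - 2))
  if (v1 <= 0 || v2 <= 0) stop("constant path: scaling exponent undefined")
  d <- 2 - (log(v2) - log(v1)) / log(2)
  list(alpha = 2 - d, fractal_dim = d, p = 1, v1 = v1, v2 = v2)
}

#' Estimate a scaling exponent by a named method
#'
#' Applies one of the four estimators used throughout the package to a
#' noise-like series (a bounded gait parameter series or fGn). DFA methods
#' integrate internally; the madogram ("MD") is applied to the cumulative
#' sum of the mean-centered series, treating it as the FBM-like path whose
#' Hurst exponent equals the series' scaling exponent.
#'
#' @param series numeric series, or a \code{\link{stride_series}}.
#' @param method one of \code{"DFA1"}, \code{"DFA2"}, \code{"DFA3"},
#'   \code{"MD"}.
#' @param window_sizes optional DFA box grid (ignored for MD).
#' @return list with \code{alpha}, \code{method}, \code{n}, and \code{detail}
#'   (the full estimator result).
#' @export
estimate_alpha <- function(series, method = c("DFA1", "DFA2", "DFA3", "MD"),
                           window_sizes = NULL) {
  method <- match.arg(method)
  y <- if (inherits(series, "stride_series")) series$values else as.numeric(series)
  detail <- if (method == "MD") {
    madogram_alpha(cumsum(y - mean(y)))
  } else {
    dfa(y, order = as.integer(substring(method, 4)), window_sizes = window_sizes)
  }
  list(alpha = detail$alpha, method = method, n = length(y), detail = detail)
}

#' Windowed scaling-exponent sweep
#'
#' Splits a series into non-overlapping windows of each length k (starting
#' at the first sample; any trailing remainder is discarded) and estimates
#' the scaling exponent per window per method.
#'
#' If \code{is_path = TRUE} the input is an FBM-like path: DFA operates on
#' the within-window increments and MD on the within-window path directly.
#' Otherwise the input is noise-like and each window is treated as in
#' \code{\link{estimate_alpha}}.
#'
#' @param series numeric vector.
#' @param k_values integer window lengths.
#' @param methods character vector among DFA1/DFA2/DFA3/MD.
#' @param is_path is \code{series} an integrated (path) signal?
#' @return object of class \code{"window_sweep"}: list with \code{k_values},
#'   \code{alphas} (named list method -> list of per-k numeric vectors) and
#'   \code{medians} (matrix method x k).
#' @export
window_sweep <- function(series, k_values, methods = c("DFA1", "MD"),
                         is_path = FALSE) {
  n <- length(series)
  k_values <- sort(unique(as.integer(k_values)))
  if (max(k_values) > n) stop("largest window exceeds series length")
  alphas <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) alphas[[m]] <- stats::setNames(
    vector("list", length(k_values)), as.character(k_values))
  for (k in k_values) {
    nb <- n %/% k
    for (b in seq_len(nb)) {
      win <- series[((b - 1) * k + 1):(b * k)]
      for (m in methods) {
        a <- tryCatch({
          if (is_path) {
            if (m == "MD") madogram_alpha(win)$alpha
            else dfa(diff(win), order = as.integer(substring(m, 4)))$alpha
          } else {
            estimate_alpha(win, m)$alpha
          }
        }, error = function(e) NA_real_)
        alphas[[m]][[as.character(k)]] <-
          c(alphas[[m]][[as.character(k)]], a)
      }
    }
  }
  med <- sapply(as.character(k_values), function(kk)
    sapply(methods, function(m) stats::median(alphas[[m]][[kk]], na.rm = TRUE)))
  med <- matrix(med, nrow = length(methods),
                dimnames = list(methods, as.character(k_values)))
  structure(list(k_values = k_values, alphas = alphas, medians = med),
            class = "window_sweep")
}

#' Windowed scaling study of an FBM ensemble
#'
#' Reproduces the finite-size behaviour of DFA and madogram estimates on
#' short fractional Brownian motion: generates an ensemble of paths, splits
#' each into non-overlapping windows of length k, estimates the exponent in
#' every window with every method, and reports per-(method, k) pooled
#' exponents and their medians.
#'
#' @param hurst Hurst exponent of the ensemble.
#' @param n_paths number of FBM paths.
#' @param length path length.
#' @param k_values window lengths (default 40 to \code{length} step 20).
#' @param methods estimators to apply.
#' @param seed integer seed.
#' @return a \code{"window_sweep"} object pooled over the ensemble.
#' @export
fbm_window_study <- function(hurst, n_paths = 500, length = 260,
                             k_values = seq(40, length, by = 20),
                             methods = c("DFA1", "MD"), seed = NULL) {
  paths <- generate_fbm(length, hurst, n_paths, seed)
  k_values <- sort(unique(as.integer(k_values)))
  alphas <- stats::setNames(vector("list", base::length(methods)), methods)
  for (m in methods) alphas[[m]] <- stats::setNames(
    vector("list", base::length(k_values)), as.character(k_values))
  for (p in seq_len(n_paths)) {
    sw <- window_sweep(paths[p, ], k_values, methods, is_path = TRUE)
    for (m in methods) for (kk in as.character(k_values))
      alphas[[m]][[kk]] <- c(alphas[[m]][[kk]], sw$alphas[[m]][[kk]])
  }
  med <- sapply(as.character(k_values), function(kk)
    sapply(methods, function(m) stats::median(alphas[[m]][[kk]], na.rm = TRUE)))
  med <- matrix(med, nrow = base::length(methods),
                dimnames = list(methods, as.character(k_values)))
  structure(list(k_values = k_values, alphas = alphas, medians = med),
            class = "window_sweep")
}

#' @export
print.window_sweep <- function(x, ...) {
  cat("Windowed scaling-exponent sweep; median alpha by method and window:\n")
  print(round(x$medians, 3))
  invisible(x)
}
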