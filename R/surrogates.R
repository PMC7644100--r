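#' Phase-randomized surrogate series
#'
#' Independent-surrogate (IS) construction: the discrete Fourier transform
#' of the series keeps its amplitude spectrum while the phases of the
#' positive frequencies are replaced by iid uniform(0, 2*pi) draws;
#' conjugate symmetry is enforced so the output is real. The DC component
#' (and for even lengths the Nyquist component) is left unchanged, so the
#' mean is preserved. Linear correlation structure (the periodogram) is
#' preserved exactly; marginal distributions are not (no amplitude
#' adjustment is performed).
#'
#' @param y numeric series, length >= 8.
#' @param seed optional integer seed.
#' @return numeric surrogate series of the same length.
#' @export
phase_randomize <- function(y, seed = NULL) {
  n <- length(y)
  if (n < 8) stop("series must have length >= 8")
  if (!is.null(seed)) set.seed(seed)
  f <- stats::fft(y)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2  # strictly positive, non-Nyquist
  idx <- seq_len(half) + 1
  phi <- stats::runif(half, 0, 2 * pi)
  f[idx] <- Mod(f[idx]) * exp(1i * phi)
  f[n + 2 - idx] <- Conj(f[idx])
  Re(stats::fft(f, inverse = TRUE)) / n
}

#' Cross-correlated phase-randomized surrogate pair
#'
#' Multi-channel phase randomization: one shared field of uniform random
#' phase increments is added to the phases of both series' spectra. Each
#' output preserves its own amplitude spectrum, and because both channels
#' are rotated by the same phases the cross-spectrum — hence the
#' cross-correlation function — is preserved to numeric tolerance.
#'
#' @param y1,y2 numeric series of equal length >= 8.
#' @param seed optional integer seed.
#' @return list with surrogate series \code{s1} and \code{s2}.
#' @export
cross_correlated_surrogates <- function(y1, y2, seed = NULL) {
  n <- length(y1)
  if (length(y2) != n) stop("series must have equal length")
  if (n < 8) stop("series must have length >= 8")
  if (!is.null(seed)) set.seed(seed)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  idx <- seq_len(half) + 1
  dphi <- stats::runif(half, 0, 2 * pi)
  rot <- function(y) {
    f <- stats::fft(y)
    f[idx] <- f[idx] * exp(1i * dphi)
    f[n + 2 - idx] <- Conj(f[idx])
    Re(stats::fft(f, inverse = TRUE)) / n
  }
  list(s1 = rot(y1), s2 = rot(y2))
}

#' Trend + shuffled-residual composite ensemble
#'
#' Builds \code{n_realizations} composite signals, each the fixed trend
#' plus an independent random permutation of the residual pool, and
#' estimates scaling exponents of every realization. Shuffling destroys
#' all serial correlation in the residuals, so any persistence measured on
#' the composites is attributable to the trend.
#'
#' @param trend numeric trend values.
#' @param residuals numeric residuals, same length.
#' @param n_realizations number of composites (default 100).
#' @param methods scaling estimators to apply per realization.
#' @param seed optional integer seed.
#' @return object of class \code{"composite_ensemble"}: \code{realizations}
#'   (n x N matrix), \code{exponents} (data.frame realization, method,
#'   alpha), \code{trend}, \code{residual_pool}.
#' @export
composite_ensemble <- function(trend, residuals, n_realizations = 100,
                               methods = c("DFA1", "MD"), seed = NULL) {
  n <- length(trend)
  if (length(residuals) != n) stop("trend and residuals must have equal length")
  if (!is.null(seed)) set.seed(seed)
  real <- t(vapply(seq_len(n_realizations),
                   function(i) trend + sample(residuals),
                   numeric(n)))
  exps <- do.call(rbind, lapply(seq_len(n_realizations), function(i) {
    data.frame(realization = i, method = methods,
               alpha = vapply(methods, function(m)
                 tryCatch(estimate_alpha(real[i, ], m)$alpha,
                          error = function(e) NA_real_), numeric(1)))
  }))
  rownames(exps) <- NULL
  structure(list(realizations = real, exponents = exps,
                 trend = trend, residual_pool = residuals),
            class = "composite_ensemble")
}

#' @export
print.composite_ensemble <- function(x, ...) {
  med <- tapply(x$exponents$alpha, x$exponents$method, stats::median,
                na.rm = TRUE)
  cat(sprintf("Composite ensemble: %d realizations of length %d\n",
              nrow(x$realizations), ncol(x$realizations)))
  cat("  median exponents:",
      paste(sprintf("%s = %.3f", names(med), med), collapse = ", "), "\n")
  invisible(x)
}

#' Compare a statistic between data and surrogate realizations
#'
#' For each of \code{n_realizations} surrogate draws, recomputes a
#' user-supplied statistic on the surrogate version of every series and
#' tests (two-sample Kolmogorov-Smirnov) whether the pooled surrogate
#' values differ from the pooled original values. Reports per-realization
#' p-values and the fraction rejected at the 0.05 level.
#'
#' @param series_set for \code{kind = "IS"} a list of numeric series; for
#'   \code{kind = "CCS"} a list of length-2 lists (the paired series).
#' @param statistic function mapping one element of \code{series_set}
#'   (series, or pair after joint surrogate generation) to a numeric
#'   vector of statistic values.
#' @param kind \code{"IS"} (independent) or \code{"CCS"}
#'   (cross-correlated pair) surrogates.
#' @param n_realizations surrogate draws (default 50).
#' @param seed optional integer seed.
#' @return list with \code{p_values}, \code{rejection_fraction},
#'   \code{original} (pooled original statistic values).
#' @export
surrogate_comparison <- function(series_set, statistic,
                                 kind = c("IS", "CCS"),
                                 n_realizations = 50, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  orig <- unlist(lapply(series_set, statistic))
  pv <- vapply(seq_len(n_realizations), function(r) {
    surr <- unlist(lapply(series_set, function(el) {
      s <- if (kind == "IS") {
        if (is.list(el)) lapply(el, phase_randomize) else phase_randomize(el)
      } else {
        if (!is.list(el) || length(el) != 2)
          stop("CCS requires elements that are pairs of series")
        cc <- cross_correlated_surrogates(el[[1]], el[[2]])
        list(cc$s1, cc$s2)
      }
      statistic(s)
    }))
    if (length(surr) == 0 || length(orig) == 0) return(NA_real_)
    suppressWarnings(stats::ks.test(orig, surr))$p.value
  }, numeric(1))
  list(p_values = pv,
       rejection_fraction = mean(pv < 0.05, na.rm = TRUE),
       original = orig)
}
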