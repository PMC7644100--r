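#' Extract trend segments from a fitted MARS model
#'
#' Converts the continuous piecewise-linear MARS trend into its linear
#' pieces: one segment between each pair of consecutive knots, plus the
#' boundary pieces before the first and after the last knot. An
#' intercept-only model (no knots) yields an empty segment list — a trial
#' with no detected trends.
#'
#' Segments tile the trial without overlap: a knot index belongs to the
#' segment on its left, so segment j > 1 owns strides
#' \code{start_idx + 1 .. end_idx} while the first owns
#' \code{start_idx .. end_idx}.
#'
#' @param model a \code{"mars"} object fitted on the stride indices of
#'   \code{series}.
#' @param series the \code{\link{stride_series}} (or numeric vector) the
#'   model was fitted to.
#' @return data.frame of class \code{"trend_segments"} with columns
#'   \code{start_idx}, \code{end_idx}, \code{delta_y}, \code{n_strides},
#'   \code{norm_duration}, \code{norm_slope}.
#' @export
extract_segments <- function(model, series) {
  stopifnot(inherits(model, "mars"))
  y <- if (inherits(series, "stride_series")) series$values else as.numeric(series)
  n <- length(y)
  knots <- sort(unique(model$terms$knot))
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0),
                      delta_y = numeric(0), n_strides = integer(0),
                      norm_duration = numeric(0), norm_slope = numeric(0))
  class(empty) <- c("trend_segments", "data.frame")
  if (length(knots) == 0) return(empty)
  bounds <- c(1, knots, n)
  trend_at <- stats::setNames(predict(model, bounds), NULL)
  mu <- mean(y)
  segs <- data.frame(start_idx = bounds[-length(bounds)],
                     end_idx = bounds[-1])
  segs$delta_y <- trend_at[-1] - trend_at[-length(trend_at)]
  owned_from <- ifelse(seq_len(nrow(segs)) == 1, segs$start_idx,
                       segs$start_idx + 1)
  segs$n_strides <- segs$end_idx - owned_from + 1L
  segs$norm_duration <- vapply(seq_len(nrow(segs)), function(j)
    sum(y[owned_from[j]:segs$end_idx[j]]) / mu, numeric(1))
  segs$norm_slope <- segs$delta_y / (mu * segs$norm_duration)
  segs <- segs[segs$n_strides >= 2, ]  # a 1-stride piece has no slope
  rownames(segs) <- NULL
  class(segs) <- c("trend_segments", "data.frame")
  segs
}

#' Normalized duration of a trend segment
#'
#' Sum of the gait-parameter values over the segment's strides divided by
#' the trial mean of the parameter — approximately the segment length in
#' strides, and exactly that for a constant series.
#'
#' @param segment one row of a \code{\link{extract_segments}} table (or any
#'   list with \code{start_idx}, \code{end_idx}).
#' @param series the stride series (values or \code{stride_series}).
#' @param first_segment does the segment start the trial (owns its first
#'   index)?
#' @return dimensionless duration > 0.
#' @export
normalized_duration <- function(segment, series, first_segment = segment$start_idx == 1) {
  y <- if (inherits(series, "stride_series")) series$values else as.numeric(series)
  from <- if (first_segment) segment$start_idx else segment$start_idx + 1
  if (segment$end_idx < from) stop("empty segment")
  sum(y[from:segment$end_idx]) / mean(y)
}

#' Normalized slope of a trend segment
#'
#' The change of the trend over the segment divided by the product of the
#' trial-mean parameter value and the normalized duration; dimensionless,
#' sign-preserving.
#'
#' @inheritParams normalized_duration
#' @return dimensionless slope.
#' @export
normalized_slope <- function(segment, series,
                             first_segment = segment$start_idx == 1) {
  y <- if (inherits(series, "stride_series")) series$values else as.numeric(series)
  nd <- normalized_duration(segment, series, first_segment)
  if (nd == 0) stop("zero normalized duration")
  segment$delta_y / (mean(y) * nd)
}

## one-sample Anderson-Darling statistic against a fully specified CDF
.ad_stat <- function(x, cdf) {
  n <- length(x)
  u <- sort(cdf(x))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  -n - mean((2 * seq_len(n) - 1) * (log(u) + log(1 - rev(u))))
}

## parametric-bootstrap p-value for the AD statistic
.ad_test <- function(x, cdf, rgen, n_boot = 200) {
  a0 <- .ad_stat(x, cdf)
  n <- length(x)
  boot <- vapply(seq_len(n_boot), function(i) .ad_stat(rgen(n), cdf),
                 numeric(1))
  (1 + sum(boot >= a0)) / (n_boot + 1)
}

#' Fit an exponential distribution to trend durations
#'
#' Maximum-likelihood fit (rate = 1 / mean) with a goodness-of-fit p-value,
#' by default from the Kolmogorov-Smirnov test against the fitted
#' distribution; \code{gof = "ad"} uses an Anderson-Darling statistic with
#' a parametric-bootstrap p-value instead.
#'
#' @param durations positive numeric values, n >= 10.
#' @param gof \code{"ks"} or \code{"ad"}.
#' @return list of class \code{"exponential_fit"}: \code{rate}, \code{n},
#'   \code{gof}, \code{gof_p}.
#' @export
fit_exponential <- function(durations, gof = c("ks", "ad")) {
  gof <- match.arg(gof)
  durations <- as.numeric(durations)
  if (length(durations) < 10) stop("need at least 10 durations")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("durations must be finite and positive")
  rate <- 1 / mean(durations)
  p <- if (gof == "ks") {
    suppressWarnings(stats::ks.test(durations, stats::pexp, rate = rate))$p.value
  } else {
    .ad_test(durations, function(q) stats::pexp(q, rate),
             function(n) stats::rexp(n, rate))
  }
  structure(list(rate = rate, n = length(durations), gof = gof, gof_p = p),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: rate = %.4g (mean %.4g), n = %d, %s p = %.3g\n",
              x$rate, 1 / x$rate, x$n, toupper(x$gof), x$gof_p))
  invisible(x)
}

#' Fit a Cauchy distribution to trend slopes
#'
#' Maximum-likelihood location and scale (numerical optimization on a
#' log-scale parametrization), with KS or Anderson-Darling goodness of fit
#' as in \code{\link{fit_exponential}}.
#'
#' @param slopes numeric values, n >= 10, not all equal.
#' @param gof \code{"ks"} or \code{"ad"}.
#' @return list of class \code{"cauchy_fit"}: \code{location},
#'   \code{scale}, \code{n}, \code{gof}, \code{gof_p}.
#' @export
fit_cauchy <- function(slopes, gof = c("ks", "ad")) {
  gof <- match.arg(gof)
  slopes <- as.numeric(slopes)
  if (length(slopes) < 10) stop("need at least 10 slopes")
  if (stats::sd(slopes) == 0) stop("degenerate sample: all values equal")
  nll <- function(p) -sum(stats::dcauchy(slopes, p[1], exp(p[2]), log = TRUE))
  start <- c(stats::median(slopes), log(max(stats::IQR(slopes) / 2, 1e-12)))
  opt <- stats::optim(start, nll)
  loc <- opt$par[1]; sc <- exp(opt$par[2])
  p <- if (gof == "ks") {
    suppressWarnings(stats::ks.test(slopes, stats::pcauchy,
                                    location = loc, scale = sc))$p.value
  } else {
    .ad_test(slopes, function(q) stats::pcauchy(q, loc, sc),
             function(n) stats::rcauchy(n, loc, sc))
  }
  structure(list(location = loc, scale = sc, n = length(slopes),
                 gof = gof, gof_p = p),
            class = "cauchy_fit")
}

#' @export
print.cauchy_fit <- function(x, ...) {
  cat(sprintf("Cauchy fit: location = %.4g, scale = %.4g, n = %d, %s p = %.3g\n",
              x$location, x$scale, x$n, toupper(x$gof), x$gof_p))
  invisible(x)
}

#' Scaling exponents of small-slope trend sections
#'
#' Selects trend segments whose normalized duration exceeds
#' \code{min_norm_len} and whose absolute normalized slope is below
#' \code{max_abs_norm_slope}, extracts the raw series over each, and
#' estimates the madogram scaling exponent of every fragment. On sections
#' where the trend is nearly flat, the exponent reflects the residual
#' fluctuations rather than the trend.
#'
#' @param segments a \code{\link{extract_segments}} table.
#' @param series the stride series the segments refer to.
#' @param min_norm_len minimum normalized duration (default 40).
#' @param max_abs_norm_slope maximum absolute normalized slope
#'   (default 0.001).
#' @return data.frame with columns \code{start_idx}, \code{end_idx},
#'   \code{norm_duration}, \code{norm_slope}, \code{alpha_md}; zero rows
#'   when no segment qualifies.
#' @export
small_slope_sections <- function(segments, series, min_norm_len = 40,
                                 max_abs_norm_slope = 0.001) {
  if (min_norm_len <= 0 || max_abs_norm_slope <= 0)
    stop("thresholds must be positive")
  y <- if (inherits(series, "stride_series")) series$values else as.numeric(series)
  sel <- segments[segments$norm_duration > min_norm_len &
                    abs(segments$norm_slope) < max_abs_norm_slope, ,
                  drop = FALSE]
  alpha <- vapply(seq_len(nrow(sel)), function(j) {
    frag <- y[sel$start_idx[j]:sel$end_idx[j]]
    estimate_alpha(frag, "MD")$alpha
  }, numeric(1))
  out <- data.frame(start_idx = sel$start_idx, end_idx = sel$end_idx,
                    norm_duration = sel$norm_duration,
                    norm_slope = sel$norm_slope,
                    alpha_md = alpha)
  rownames(out) <- NULL
  out
}

#' Tidy table of segments from several trials
#'
#' @param segment_list named list of \code{trend_segments} tables.
#' @param parameter gait parameter label attached to every row.
#' @return a single data.frame with \code{trial_id} and \code{parameter}
#'   columns prepended, ready for \code{write.csv}.
#' @export
segments_table <- function(segment_list, parameter = "ST") {
  ids <- names(segment_list)
  if (is.null(ids)) ids <- as.character(seq_along(segment_list))
  do.call(rbind, lapply(seq_along(segment_list), function(i) {
    s <- as.data.frame(segment_list[[i]])
    if (nrow(s) == 0) return(NULL)
    cbind(trial_id = ids[i], parameter = parameter, s)
  }))
}
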