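#' Stride series container
#'
#' One gait parameter's per-stride values plus trial metadata.
#'
#' @param values strictly positive numeric vector (one value per stride).
#' @param parameter one of \code{"ST"} (stride time, s), \code{"SL"}
#'   (stride length, m), \code{"SS"} (stride speed, m/s).
#' @param subject_id,trial_id identifier strings.
#' @param pws_percent treadmill speed as percent of preferred walking speed.
#' @param treadmill_speed nominal belt speed in m/s (optional).
#' @return object of class \code{"stride_series"}.
#' @export
stride_series <- function(values, parameter = c("ST", "SL", "SS"),
                          subject_id = "S1", trial_id = "T1",
                          pws_percent = 100L, treadmill_speed = NULL) {
  parameter <- match.arg(parameter)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("stride series values must be finite and strictly positive")
  structure(list(values = values, parameter = parameter,
                 subject_id = subject_id, trial_id = trial_id,
                 pws_percent = as.integer(pws_percent),
                 treadmill_speed = treadmill_speed),
            class = "stride_series")
}

#' @export
print.stride_series <- function(x, ...) {
  u <- c(ST = "s", SL = "m", SS = "m/s")[x$parameter]
  cat(sprintf("Stride series: %s [%s], %d strides, mean %.3f (subject %s, trial %s)\n",
              x$parameter, u, length(x$values), mean(x$values),
              x$subject_id, x$trial_id))
  invisible(x)
}

#' @export
length.stride_series <- function(x) length(x$values)

#' Specification of a synthetic gait trial
#'
#' Parameters of the coupled stride-time / stride-length generator. The
#' defaults emulate a 5-minute treadmill trial at preferred walking speed:
#' piecewise-linear trends with exponentially distributed normalized
#' durations and Cauchy-distributed normalized slopes (shared knots,
#' correlated slope draws), plus fractional-Gaussian-noise residuals.
#'
#' @param n_strides strides per trial.
#' @param treadmill_speed belt speed, m/s.
#' @param mean_st mean stride time, s. Mean stride length is constructed as
#'   \code{treadmill_speed * mean_st}.
#' @param duration_rate rate of the exponential distribution of normalized
#'   trend durations (in strides); the mean trend lasts
#'   \code{1/duration_rate} strides.
#' @param slope_scale_st,slope_scale_sl Cauchy scale of normalized slopes.
#' @param slope_location_st,slope_location_sl Cauchy location of normalized
#'   slopes.
#' @param trend_correlation target correlation between ST and SL trends,
#'   imposed through a Gaussian copula on the per-segment slope draws.
#' @param residual_hurst Hurst exponent of the fGn residuals.
#' @param residual_cv residual coefficient of variation (sd / mean).
#' @param seed integer seed.
#' @return list of class \code{"gait_trial_spec"}.
#' @export
gait_trial_spec <- function(n_strides = 260, treadmill_speed = 1.25,
                            mean_st = 1.12,
                            duration_rate = 0.043,
                            slope_scale_st = 1.2e-3, slope_scale_sl = 1.5e-3,
                            slope_location_st = 8e-4, slope_location_sl = 6e-4,
                            trend_correlation = 0.79,
                            residual_hurst = 0.48, residual_cv = 0.015,
                            seed = NULL) {
  if (duration_rate <= 0) stop("'duration_rate' must be > 0")
  if (slope_scale_st <= 0 || slope_scale_sl <= 0) stop("slope scales must be > 0")
  if (abs(trend_correlation) > 1) stop("'trend_correlation' must be in [-1, 1]")
  if (residual_hurst <= 0 || residual_hurst >= 1)
    stop("'residual_hurst' must be in (0, 1)")
  if (n_strides < 4) stop("'n_strides' must be >= 4")
  structure(list(n_strides = as.integer(n_strides),
                 treadmill_speed = treadmill_speed, mean_st = mean_st,
                 mean_sl = treadmill_speed * mean_st,
                 duration_rate = duration_rate,
                 slope_scale_st = slope_scale_st,
                 slope_scale_sl = slope_scale_sl,
                 slope_location_st = slope_location_st,
                 slope_location_sl = slope_location_sl,
                 trend_correlation = trend_correlation,
                 residual_hurst = residual_hurst,
                 residual_cv = residual_cv, seed = seed),
            class = "gait_trial_spec")
}

## piecewise-linear trends through shared knots. Per-segment normalized
## slopes are Cauchy draws (truncated at +/- 20 scale) coupled across ST/SL
## by a Gaussian copula; the copula correlation is sin(pi * rho / 2) so that
## the requested value acts at the concordance (Kendall) level, which
## compensates the correlation-damping of the heavy-tailed margins. Both
## trends evolve inside a band of +/- 5% of the trial mean (the belt speed
## constrains how far gait parameters can wander): a step that would leave
## the band has its sign reflected jointly for ST and SL, preserving both
## the slope-magnitude distribution and the slope coupling; a residual
## excursion is clamped to the band edge.
.trial_trends <- function(spec, band = 0.05) {
  n <- spec$n_strides
  # shared knot layout: exponential normalized durations, >= 2 strides
  durs <- integer(0)
  while (sum(durs) < n) {
    d <- max(2L, as.integer(round(stats::rexp(1, spec$duration_rate))))
    durs <- c(durs, d)
  }
  knots <- cumsum(durs)
  knots <- c(1L, knots[knots < n], n)  # boundaries incl. both ends
  nseg <- length(knots) - 1L
  rho_c <- sin(pi * spec$trend_correlation / 2)
  z1 <- stats::rnorm(nseg)
  z2 <- rho_c * z1 + sqrt(max(0, 1 - rho_c^2)) * stats::rnorm(nseg)
  clip <- function(s, loc, sc) pmin(pmax(s, loc - 20 * sc), loc + 20 * sc)
  s_st <- clip(stats::qcauchy(stats::pnorm(z1), spec$slope_location_st,
                              spec$slope_scale_st),
               spec$slope_location_st, spec$slope_scale_st)
  s_sl <- clip(stats::qcauchy(stats::pnorm(z2), spec$slope_location_sl,
                              spec$slope_scale_sl),
               spec$slope_location_sl, spec$slope_scale_sl)
  mu1 <- spec$mean_st; mu2 <- spec$mean_sl
  v1 <- numeric(nseg + 1L); v1[1] <- mu1
  v2 <- numeric(nseg + 1L); v2[1] <- mu2
  for (j in seq_len(nseg)) {
    dur <- knots[j + 1L] - knots[j]
    p1 <- v1[j] + s_st[j] * mu1 * dur
    p2 <- v2[j] + s_sl[j] * mu2 * dur
    out1 <- p1 < (1 - band) * mu1 || p1 > (1 + band) * mu1
    out2 <- p2 < (1 - band) * mu2 || p2 > (1 + band) * mu2
    if (out1 || out2) {  # joint sign reflection keeps the pair coupled
      s_st[j] <- -s_st[j]; s_sl[j] <- -s_sl[j]
      p1 <- v1[j] + s_st[j] * mu1 * dur
      p2 <- v2[j] + s_sl[j] * mu2 * dur
    }
    v1[j + 1L] <- pmin(pmax(p1, (1 - band) * mu1), (1 + band) * mu1)
    v2[j + 1L] <- pmin(pmax(p2, (1 - band) * mu2), (1 + band) * mu2)
  }
  list(knots = knots[-c(1, length(knots))],
       st = stats::approx(knots, v1, xout = seq_len(n))$y,
       sl = stats::approx(knots, v2, xout = seq_len(n))$y)
}

#' Generate a coupled synthetic gait trial
#'
#' Builds stride-time and stride-length series as continuous piecewise-
#' linear trends plus fractional-Gaussian-noise residuals, with shared
#' trend knots and correlated per-segment slopes; stride speed is the
#' elementwise ratio SL/ST. Ground-truth trends and knots are kept in the
#' returned object for recovery tests.
#'
#' @param spec a \code{\link{gait_trial_spec}}.
#' @return object of class \code{"gait_trial"}: stride series \code{st},
#'   \code{sl}, \code{ss}; ground truth \code{true_st_trend},
#'   \code{true_sl_trend}, \code{true_knots}; and the \code{spec}.
#' @examples
#' trial <- generate_gait_trial(gait_trial_spec(seed = 1))
#' trial
#' @export
generate_gait_trial <- function(spec) {
  stopifnot(inherits(spec, "gait_trial_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  tr <- .trial_trends(spec)
  n <- spec$n_strides
  noise <- function(mu) {
    if (spec$residual_cv == 0) return(numeric(n))
    e <- generate_fgn(n, spec$residual_hurst, 1)[1, ]
    e / stats::sd(e) * spec$residual_cv * mu
  }
  for (attempt in 1:20) {
    st <- tr$st + noise(spec$mean_st)
    sl <- tr$sl + noise(spec$mean_sl)
    if (all(st > 0) && all(sl > 0)) {
      meta <- list(pws_percent = 100L, treadmill_speed = spec$treadmill_speed)
      return(structure(list(
        st = stride_series(st, "ST", pws_percent = meta$pws_percent,
                           treadmill_speed = meta$treadmill_speed),
        sl = stride_series(sl, "SL", pws_percent = meta$pws_percent,
                           treadmill_speed = meta$treadmill_speed),
        ss = stride_series(sl / st, "SS", pws_percent = meta$pws_percent,
                           treadmill_speed = meta$treadmill_speed),
        true_st_trend = tr$st, true_sl_trend = tr$sl,
        true_knots = tr$knots, spec = spec),
        class = "gait_trial"))
    }
  }
  stop("could not generate a strictly positive trial; lower residual_cv")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("Synthetic gait trial: %d strides, belt %.2f m/s, %d trend knot(s)\n",
              length(x$st$values), x$spec$treadmill_speed,
              length(x$true_knots)))
  cat(sprintf("  mean ST %.3f s, mean SL %.3f m, mean SS %.3f m/s\n",
              mean(x$st$values), mean(x$sl$values), mean(x$ss$values)))
  invisible(x)
}

#' Write a gait trial to CSV
#'
#' Columns: stride_index, st_s, sl_m, ss_mps, true_st_trend, true_sl_trend.
#'
#' @param trial a \code{"gait_trial"}.
#' @param path output file path.
#' @export
write_gait_trial <- function(trial, path) {
  df <- data.frame(stride_index = seq_along(trial$st$values),
                   st_s = trial$st$values, sl_m = trial$sl$values,
                   ss_mps = trial$ss$values,
                   true_st_trend = trial$true_st_trend,
                   true_sl_trend = trial$true_sl_trend)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gait trial CSV
#'
#' Reads a per-trial CSV with columns stride_index, st_s, sl_m and
#' optionally ss_mps (computed as sl_m / st_s when absent). Ground-truth
#' trend columns written by \code{\link{write_gait_trial}} are restored
#' when present.
#'
#' @param path CSV file path.
#' @param subject_id,trial_id,pws_percent metadata to attach.
#' @return a list with stride series \code{st}, \code{sl}, \code{ss} (and
#'   ground-truth trends when present in the file).
#' @export
read_gait_trial <- function(path, subject_id = "S1", trial_id = "T1",
                            pws_percent = 100L) {
  df <- utils::read.csv(path)
  if (!all(c("st_s", "sl_m") %in% names(df)))
    stop("CSV must contain columns 'st_s' and 'sl_m'")
  ss <- if ("ss_mps" %in% names(df)) df$ss_mps else df$sl_m / df$st_s
  out <- list(
    st = stride_series(df$st_s, "ST", subject_id, trial_id, pws_percent),
    sl = stride_series(df$sl_m, "SL", subject_id, trial_id, pws_percent),
    ss = stride_series(ss, "SS", subject_id, trial_id, pws_percent))
  if ("true_st_trend" %in% names(df)) out$true_st_trend <- df$true_st_trend
  if ("true_sl_trend" %in% names(df)) out$true_sl_trend <- df$true_sl_trend
  out
}
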