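#' Trend speed
#'
#' Per-stride ratio of the stride-length trend to the stride-time trend:
#' the speed implied by the smooth trends alone.
#'
#' @param st_trend stride-time trend values (s), strictly positive.
#' @param sl_trend stride-length trend values (m), same length.
#' @return numeric vector of trend speeds (m/s).
#' @export
trend_speed <- function(st_trend, sl_trend) {
  if (length(st_trend) != length(sl_trend))
    stop("trends must have equal length")
  if (any(st_trend <= 0)) stop("stride-time trend must be strictly positive")
  sl_trend / st_trend
}

#' Trend speed control parameter
#'
#' Normalized squared deviation of the trend speed from the trial-mean
#' stride speed:
#' \deqn{TSC = \frac{\sum_i (v_i^{(trend)} - \langle SS\rangle)^2}
#'                  {N \langle SS\rangle^2}.}
#' Zero iff the trend speed equals the mean stride speed at every stride.
#' \code{sqrt = TRUE} returns the RMS variant (the square root).
#'
#' @param v_trend trend-speed series from \code{\link{trend_speed}}.
#' @param ss measured stride-speed series (m/s), same length; its mean is
#'   \eqn{\langle SS\rangle}.
#' @param sqrt return the square root of the statistic?
#' @return non-negative scalar.
#' @export
tsc <- function(v_trend, ss, sqrt = FALSE) {
  if (length(v_trend) != length(ss)) stop("series must have equal length")
  if (inherits(ss, "stride_series")) ss <- ss$values
  m <- mean(ss)
  if (m == 0) stop("mean stride speed is zero")
  val <- sum((v_trend - m)^2) / (length(ss) * m^2)
  if (sqrt) base::sqrt(val) else val
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean, as a fraction.
#'
#' @param x numeric vector or \code{stride_series} with non-zero mean.
#' @return scalar COV.
#' @export
coefficient_of_variation <- function(x) {
  if (inherits(x, "stride_series")) x <- x$values
  m <- mean(x)
  if (m == 0) stop("mean is zero; COV undefined")
  stats::sd(x) / m
}

#' ST-SL correlations at three levels
#'
#' Pearson correlations between stride time and stride length computed for
#' the raw series, the fitted MARS trends, and the MARS residuals (noise).
#'
#' @param st,sl stride series (values or \code{stride_series}).
#' @param st_model,sl_model fitted \code{"mars"} models for the two series.
#' @return list with \code{rho_raw}, \code{rho_trend}, \code{rho_noise}.
#' @export
correlations <- function(st, sl, st_model, sl_model) {
  x <- if (inherits(st, "stride_series")) st$values else as.numeric(st)
  y <- if (inherits(sl, "stride_series")) sl$values else as.numeric(sl)
  if (length(x) != length(y)) stop("series must have equal length")
  list(rho_raw = stats::cor(x, y),
       rho_trend = suppressWarnings(stats::cor(st_model$fitted, sl_model$fitted)),
       rho_noise = stats::cor(st_model$residuals, sl_model$residuals))
}

#' Full per-trial gait analysis
#'
#' Fits a piecewise-linear MARS trend to stride time and stride length,
#' splits each series into trend + residual, estimates all scaling
#' exponents (raw and residual, DFA1/DFA2/DFA3 and madogram), extracts
#' trend segments, and computes the trend speed, the TSC parameter,
#' coefficients of variation, and the three-level ST-SL correlations.
#'
#' An intercept-only MARS fit (no detected trend) gives a constant trend
#' equal to the series mean, an empty segment list, and residuals equal to
#' the mean-centered series; the analysis still completes.
#'
#' @param st,sl stride-time and stride-length \code{\link{stride_series}}
#'   (or numeric vectors).
#' @param ss stride-speed series; computed as sl / st when \code{NULL}.
#' @param config a \code{\link{mars_config}} for the trend fits.
#' @param methods scaling estimators to apply.
#' @return object of class \code{"trial_analysis"}.
#' @export
analyze_trial <- function(st, sl, ss = NULL, config = mars_config(),
                          methods = c("DFA1", "DFA2", "DFA3", "MD")) {
  stv <- if (inherits(st, "stride_series")) st$values else as.numeric(st)
  slv <- if (inherits(sl, "stride_series")) sl$values else as.numeric(sl)
  if (length(stv) != length(slv)) stop("ST and SL must have equal length")
  ssv <- if (is.null(ss)) slv / stv
         else if (inherits(ss, "stride_series")) ss$values else as.numeric(ss)
  n <- length(stv)
  x <- seq_len(n)
  st_model <- fit_mars(x, stv, config)
  sl_model <- fit_mars(x, slv, config)
  segs <- list(ST = extract_segments(st_model, stv),
               SL = extract_segments(sl_model, slv))
  est <- function(y, par, sig) {
    do.call(rbind, lapply(methods, function(m) {
      a <- tryCatch(estimate_alpha(y, m)$alpha, error = function(e) NA_real_)
      data.frame(parameter = par, signal = sig, method = m, alpha = a)
    }))
  }
  exponents <- rbind(est(stv, "ST", "raw"), est(st_model$residuals, "ST", "residual"),
                     est(slv, "SL", "raw"), est(sl_model$residuals, "SL", "residual"))
  rownames(exponents) <- NULL
  v_tr <- trend_speed(st_model$fitted, sl_model$fitted)
  structure(list(
    st_model = st_model, sl_model = sl_model, segments = segs,
    exponents = exponents,
    trend_speed = v_tr,
    tsc = tsc(v_tr, ssv),
    cov = list(trend_speed = coefficient_of_variation(v_tr),
               SS = coefficient_of_variation(ssv),
               SL = coefficient_of_variation(slv),
               ST = coefficient_of_variation(stv)),
    correlations = correlations(stv, slv, st_model, sl_model),
    n = n), class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("Gait trial analysis (%d strides)\n", x$n))
  cat(sprintf("  trend knots: ST %d, SL %d\n",
              length(unique(x$st_model$terms$knot)),
              length(unique(x$sl_model$terms$knot))))
  md <- x$exponents[x$exponents$method == "MD", ]
  for (p in c("ST", "SL")) {
    r <- md[md$parameter == p, ]
    cat(sprintf("  %s alpha(MD): raw %.2f, residual %.2f\n", p,
                r$alpha[r$signal == "raw"], r$alpha[r$signal == "residual"]))
  }
  cat(sprintf("  TSC = %.4g; COV: v_trend %.2f%%, SS %.2f%%, SL %.2f%%, ST %.2f%%\n",
              x$tsc, 100 * x$cov$trend_speed, 100 * x$cov$SS,
              100 * x$cov$SL, 100 * x$cov$ST))
  cat(sprintf("  rho: raw %.2f, trend %.2f, noise %.2f\n",
              x$correlations$rho_raw, x$correlations$rho_trend,
              x$correlations$rho_noise))
  invisible(x)
}

#' Group statistics for trial-level quantities
#'
#' Thin delegation to the standard tests used for gait trend analyses:
#' Shapiro-Wilk normality per group, Kruskal-Wallis across groups with
#' pairwise Wilcoxon post hoc comparisons (Holm-adjusted), one-way ANOVA
#' with Tukey HSD, pairwise two-sample Kolmogorov-Smirnov tests, and
#' left-sided one-sample t and Wilcoxon signed-rank tests against the
#' reference value 0.5 (the anti-persistence check for scaling exponents).
#' Tests whose sample-size requirements are not met are skipped with a
#' note in the table.
#'
#' @param values numeric vector of a per-trial quantity.
#' @param groups factor/vector of group labels (e.g. treadmill speed).
#' @param tests subset of
#'   \code{c("shapiro", "kruskal", "anova", "ks", "vs_half")}.
#' @return tidy data.frame: \code{test}, \code{groups}, \code{statistic},
#'   \code{p}, \code{note}.
#' @export
group_statistics <- function(values, groups,
                             tests = c("shapiro", "kruskal", "anova",
                                       "ks", "vs_half")) {
  groups <- as.factor(groups)
  rows <- list()
  add <- function(test, grp, stat, p, note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      test = test, groups = grp, statistic = stat, p = p, note = note)
  }
  lv <- levels(groups)
  if ("shapiro" %in% tests) {
    for (g in lv) {
      v <- values[groups == g]
      if (length(v) >= 3 && stats::sd(v) > 0) {
        s <- stats::shapiro.test(v)
        add("shapiro", g, unname(s$statistic), s$p.value)
      } else add("shapiro", g, NA, NA, "skipped: n < 3 or constant")
    }
  }
  if ("kruskal" %in% tests) {
    if (length(lv) >= 2) {
      k <- stats::kruskal.test(values, groups)
      add("kruskal", paste(lv, collapse = "|"), unname(k$statistic), k$p.value)
      pw <- suppressWarnings(
        stats::pairwise.wilcox.test(values, groups, p.adjust.method = "holm"))
      pm <- pw$p.value
      for (i in rownames(pm)) for (j in colnames(pm))
        if (!is.na(pm[i, j]))
          add("wilcox_posthoc", paste(i, j, sep = "|"), NA, pm[i, j])
    } else add("kruskal", "", NA, NA, "skipped: single group")
  }
  if ("anova" %in% tests) {
    if (length(lv) >= 2 && all(table(groups) >= 2)) {
      fit <- stats::aov(values ~ groups)
      an <- summary(fit)[[1]]
      add("anova", paste(lv, collapse = "|"), an$`F value`[1], an$`Pr(>F)`[1])
      tk <- stats::TukeyHSD(fit)$groups
      for (i in rownames(tk))
        add("tukey_hsd", i, tk[i, "diff"], tk[i, "p adj"])
    } else add("anova", "", NA, NA, "skipped: need >= 2 groups with n >= 2")
  }
  if ("ks" %in% tests && length(lv) >= 2) {
    cmb <- utils::combn(lv, 2)
    for (c_i in seq_len(ncol(cmb))) {
      a <- values[groups == cmb[1, c_i]]; b <- values[groups == cmb[2, c_i]]
      if (length(a) >= 2 && length(b) >= 2) {
        k <- suppressWarnings(stats::ks.test(a, b))
        add("ks", paste(cmb[, c_i], collapse = "|"),
            unname(k$statistic), k$p.value)
      }
    }
  }
  if ("vs_half" %in% tests) {
    for (g in lv) {
      v <- values[groups == g]
      if (length(v) >= 3 && stats::sd(v) > 0) {
        tt <- stats::t.test(v, mu = 0.5, alternative = "less")
        add("t_vs_0.5_less", g, unname(tt$statistic), tt$p.value)
        w <- suppressWarnings(
          stats::wilcox.test(v, mu = 0.5, alternative = "less"))
        add("wilcoxon_vs_0.5_less", g, unname(w$statistic), w$p.value)
      } else add("t_vs_0.5_less", g, NA, NA, "skipped: n < 3 or constant")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
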