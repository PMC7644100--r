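#' MARS configuration
#'
#' Settings for the one-dimensional additive piecewise-linear MARS fit.
#'
#' @param stop_threshold forward-pass stopping condition: the pass stops when
#'   the relative reduction of the residual sum of squares (as a fraction of
#'   the total sum of squares) achieved by the best candidate pair falls
#'   below this value. Default 0.001.
#' @param gcv_penalty_c knot penalty c in the effective number of parameters
#'   M = r + cK used by generalized cross-validation. Default 2, the usual
#'   value for additive models.
#' @param max_terms ceiling on the number of basis functions (including the
#'   intercept). Default 21.
#' @return list of class \code{"mars_config"}.
#' @export
mars_config <- function(stop_threshold = 0.001, gcv_penalty_c = 2,
                        max_terms = 21) {
  if (stop_threshold <= 0) stop("'stop_threshold' must be > 0")
  if (gcv_penalty_c < 0) stop("'gcv_penalty_c' must be >= 0")
  if (max_terms < 1) stop("'max_terms' must be >= 1")
  structure(list(stop_threshold = stop_threshold,
                 gcv_penalty_c = gcv_penalty_c,
                 max_terms = max_terms),
            class = "mars_config")
}

## hinge basis columns for a term table (data.frame knot, direction in {1,-1})
.mars_basis <- function(x, terms) {
  if (nrow(terms) == 0) return(matrix(1, length(x), 1))
  cols <- vapply(seq_len(nrow(terms)), function(i) {
    t <- terms$knot[i]
    if (terms$direction[i] > 0) pmax(0, x - t) else pmax(0, t - x)
  }, numeric(length(x)))
  cbind(1, cols)
}

## least-squares fit of y on basis B; returns coef (NA-free), sse, rank
.mars_ls <- function(B, y) {
  fit <- stats::lm.fit(B, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(beta = beta, sse = sum(fit$residuals^2), rank = fit$rank)
}

.mars_gcv <- function(sse, n, r, k, c) {
  m_eff <- r + c * k
  if (m_eff >= n) return(Inf)
  sse / (1 - m_eff / n)^2
}

## assemble a "mars" object from a term table + config
.mars_build <- function(x, y, terms, config) {
  B <- .mars_basis(x, terms)
  ls <- .mars_ls(B, y)
  fitted <- drop(B %*% ls$beta)
  k <- length(unique(terms$knot))
  gcv <- .mars_gcv(ls$sse, length(y), ls$rank, k, config$gcv_penalty_c)
  terms$coefficient <- if (nrow(terms)) ls$beta[-1] else numeric(0)
  structure(list(intercept = unname(ls$beta[1]),
                 terms = terms,
                 n_terms = nrow(terms) + 1L,
                 gcv = gcv,
                 effective_params = ls$rank + config$gcv_penalty_c * k,
                 fitted = fitted,
                 residuals = y - fitted,
                 sse = ls$sse,
                 x = x, y = y,
                 config = config),
            class = "mars")
}

.empty_terms <- function() {
  data.frame(knot = numeric(0), direction = integer(0),
             coefficient = numeric(0))
}

#' Forward pass of the additive piecewise-linear MARS algorithm
#'
#' Greedily grows the model from the intercept by repeatedly adding the
#' reflected pair of hinge functions max(0, x - t), max(0, t - x) whose
#' knot t gives the largest reduction of the residual sum of squares, with
#' all coefficients re-estimated by least squares at every step. Candidate
#' knots are the interior abscissa values. The model is additive (maximum
#' interaction order 1). The pass stops when the relative error reduction
#' falls below \code{config$stop_threshold} or the term ceiling is reached.
#'
#' @param x strictly increasing numeric abscissa (e.g. stride index 1..N).
#' @param y numeric response, same length as x (length >= 4).
#' @param config a \code{\link{mars_config}}.
#' @return an (unpruned) object of class \code{"mars"}.
#' @export
forward_pass <- function(x, y, config = mars_config()) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 4) stop("need at least 4 observations")
  if (any(diff(x) <= 0)) stop("'x' must be strictly increasing (no duplicates)")
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  terms <- .empty_terms()
  B <- matrix(1, n, 1)
  sse <- sum(stats::lm.fit(B, y)$residuals^2)
  if (sst == 0) return(.mars_build(x, y, terms, config))
  candidates <- x[-c(1, n)]
  repeat {
    if (nrow(terms) + 1L + 2L > config$max_terms) break
    avail <- setdiff(candidates, terms$knot)
    if (!length(avail)) break
    rank_cur <- qr(B)$rank
    best <- NULL
    for (t in avail) {
      h1 <- pmax(0, x - t); h2 <- pmax(0, t - x)
      Bc <- cbind(B, h1, h2)
      fit <- stats::lm.fit(Bc, y)
      # a second reflected pair is always partly collinear with the first
      # (each pair spans the global line); require only that the candidate
      # adds information, not that the design stays full rank
      if (fit$rank <= rank_cur) next
      s <- sum(fit$residuals^2)
      # tie-break: strictly better required, so the first (smallest) knot
      # among equals wins (avail is sorted ascending)
      if (is.null(best) || s < best$sse - 1e-12 * sst) best <- list(t = t, sse = s)
    }
    if (is.null(best)) break
    if ((sse - best$sse) / sst < config$stop_threshold) break
    terms <- rbind(terms,
                   data.frame(knot = c(best$t, best$t),
                              direction = c(1L, -1L),
                              coefficient = c(0, 0)))
    B <- .mars_basis(x, terms)
    sse <- best$sse
  }
  .mars_build(x, y, terms, config)
}

#' Backward pruning by generalized cross-validation
#'
#' Starting from a forward-pass model, repeatedly deletes the single basis
#' function whose removal causes the smallest increase in the residual sum
#' of squares, producing a nested deletion sequence down to the intercept-
#' only model, and returns the model in the sequence with the smallest
#' generalized cross-validation score
#' \deqn{GCV(\lambda) = \frac{\sum_i (y_i - \hat f_\lambda(x_i))^2}
#'                          {(1 - M(\lambda)/N)^2},}
#' where the effective number of parameters is M = r + cK (r independent
#' basis functions, K knots, penalty c from the configuration).
#'
#' @param model a \code{"mars"} object from \code{\link{forward_pass}}.
#' @return the pruned \code{"mars"} model minimizing GCV.
#' @export
backward_prune <- function(model) {
  stopifnot(inherits(model, "mars"))
  x <- model$x; y <- model$y; config <- model$config
  terms <- model$terms
  best <- model
  current <- terms
  while (nrow(current) > 0) {
    # delete the term whose removal raises SSE least
    sse_del <- vapply(seq_len(nrow(current)), function(i) {
      .mars_ls(.mars_basis(x, current[-i, , drop = FALSE]), y)$sse
    }, numeric(1))
    drop_i <- which.min(sse_del)
    current <- current[-drop_i, , drop = FALSE]
    cand <- .mars_build(x, y, current, config)
    if (cand$gcv <= best$gcv) best <- cand
  }
  # numeric hygiene: drop lone pair members with negligible coefficients
  scale <- stats::sd(y)
  if (nrow(best$terms) > 0 && scale > 0) {
    keep <- abs(best$terms$coefficient) > 1e-12 * scale
    if (!all(keep))
      best <- .mars_build(x, y, best$terms[keep, , drop = FALSE], config)
  }
  best
}

#' Fit a piecewise-linear additive MARS trend
#'
#' The package's central model fit: the forward model-building pass followed
#' by GCV backward pruning. The result is an explicit continuous piecewise-
#' linear trend in \code{x}, suitable for extracting trend segments
#' (\code{\link{extract_segments}}) and detrending gait series.
#'
#' @param x strictly increasing abscissa; for gait series the stride index.
#' @param y numeric response (e.g. stride times in seconds).
#' @param config a \code{\link{mars_config}}.
#' @return object of class \code{"mars"} with components \code{intercept},
#'   \code{terms} (knot, direction, coefficient), \code{fitted},
#'   \code{residuals}, \code{gcv}, \code{effective_params}, \code{n_terms}.
#' @examples
#' x <- 1:100
#' y <- abs(x - 50) / 25 + rnorm(100, sd = 0.05)
#' m <- fit_mars(x, y)
#' m
#' @export
fit_mars <- function(x, y, config = mars_config()) {
  backward_prune(forward_pass(x, y, config))
}

#' @export
predict.mars <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  drop(.mars_basis(x, object$terms) %*%
         c(object$intercept, object$terms$coefficient))
}

#' @export
fitted.mars <- function(object, ...) object$fitted

#' @export
residuals.mars <- function(object, ...) object$residuals

#' @export
coef.mars <- function(object, ...) {
  tt <- object$terms
  nm <- if (nrow(tt)) ifelse(tt$direction > 0,
                             sprintf("h(x-%g)", tt$knot),
                             sprintf("h(%g-x)", tt$knot)) else character(0)
  stats::setNames(c(object$intercept, tt$coefficient), c("(Intercept)", nm))
}

#' @export
print.mars <- function(x, ...) {
  k <- length(unique(x$terms$knot))
  cat(sprintf("Piecewise-linear MARS model: %d basis function(s), %d knot(s)\n",
              x$n_terms, k))
  cat(sprintf("  GCV = %.6g, effective parameters = %.1f\n",
              x$gcv, x$effective_params))
  if (k > 0) cat("  knots:", paste(sort(unique(x$terms$knot)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mars <- function(object, ...) {
  out <- list(coef = coef(object),
              knots = sort(unique(object$terms$knot)),
              gcv = object$gcv,
              effective_params = object$effective_params,
              rss = sum(object$residuals^2),
              n = length(object$y))
  class(out) <- "summary.mars"
  out
}

#' @export
print.summary.mars <- function(x, ...) {
  cat("Piecewise-linear MARS fit\n")
  cat(sprintf("  n = %d, RSS = %.6g, GCV = %.6g, M(lambda) = %.1f\n",
              x$n, x$rss, x$gcv, x$effective_params))
  cat("  coefficients:\n")
  print(x$coef)
  invisible(x)
}

#' @export
plot.mars <- function(x, ...) {
  graphics::plot(x$x, x$y, col = "grey50", pch = 16, cex = 0.5,
                 xlab = "x", ylab = "y", ...)
  graphics::lines(x$x, x$fitted, lwd = 2)
  kn <- unique(x$terms$knot)
  if (length(kn)) graphics::abline(v = kn, lty = 3, col = "grey70")
  invisible(x)
}

#' Serialize a MARS model to JSON
#'
#' @param model a \code{"mars"} object.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
mars_to_json <- function(model, path = NULL) {
  obj <- list(intercept = model$intercept,
              terms = data.frame(
                knot = model$terms$knot,
                direction = ifelse(model$terms$direction > 0, "+", "-"),
                coefficient = model$terms$coefficient),
              config = unclass(model$config),
              gcv = model$gcv)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Rebuild a MARS model from JSON
#'
#' Restores a model serialized with \code{\link{mars_to_json}} and, given
#' the training data, recomputes fitted values and diagnostics.
#'
#' @param json JSON string or file path.
#' @param x,y training data used to refit diagnostics.
#' @return a \code{"mars"} object.
#' @export
mars_from_json <- function(json, x, y) {
  obj <- jsonlite::fromJSON(json)
  cfg <- do.call(mars_config, obj$config)
  terms <- if (length(obj$terms)) {
    data.frame(knot = obj$terms$knot,
               direction = ifelse(obj$terms$direction == "+", 1L, -1L),
               coefficient = obj$terms$coefficient)
  } else .empty_terms()
  .mars_build(x, y, terms, cfg)
}
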