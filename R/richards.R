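#' Evaluate the Richards generalized logistic growth curve
#'
#' Computes the four-parameter Richards (generalized logistic) curve
#' \deqn{y(x) = a\,[1 + (d - 1)\, e^{-k (x - x_c)}]^{1/(1-d)}, \quad d \neq 1,}
#' the sigmoid used to describe optical-density growth kinetics. \code{a} is
#' the upper asymptote (OD units), \code{k} the growth-rate constant (1/day),
#' \code{d} a dimensionless shape parameter and \code{xc} the inflection time
#' (days). With \code{d = 2} the curve reduces to the ordinary logistic
#' \code{a / (1 + exp(-k (x - xc)))}; at \code{x = xc} the value is
#' \code{a * d^(1/(1-d))} (i.e. \code{a/2} for the logistic case).
#'
#' Only the sigmoid branch \code{d > 1} is admitted: for \code{0 < d < 1} the
#' same formula describes a decaying curve, which has no place in a growth
#' assay, and \code{d = 1} is a singularity of the exponent.
#'
#' @param x time (days); numeric vector.
#' @param a upper asymptote, must be > 0.
#' @param k growth rate constant (1/day), must be > 0.
#' @param d shape parameter, must be > 1.
#' @param xc inflection time (days), finite.
#' @return Numeric vector of curve values, same length as \code{x}.
#' @examples
#' richards(10, a = 1, k = 0.6, d = 2, xc = 10)  # 0.5 at the inflection
#' @export
richards <- function(x, a, k, d, xc) {
  check_richards_params(a, k, d, xc)
  a * (1 + (d - 1) * exp(-k * (x - xc)))^(1 / (1 - d))
}

check_richards_params <- function(a, k, d, xc) {
  if (!is.finite(a) || a <= 0) stop("'a' (upper asymptote) must be finite and > 0")
  if (!is.finite(k) || k <= 0) stop("'k' (rate constant) must be finite and > 0")
  if (!is.finite(d)) stop("'d' (shape) must be finite")
  if (d == 1) stop("'d' = 1 is outside the model's domain (d != 1)")
  if (d <= 1) stop("'d' must be > 1 (sigmoid branch); decaying branch 0 < d < 1 is rejected")
  if (!is.finite(xc)) stop("'xc' (inflection time) must be finite")
  invisible(TRUE)
}

#' Normalized average growth rate of a fitted Richards curve
#'
#' The summary statistic used to compare treatments: \eqn{k / (2 (d + 1))}
#' (1/day). It is strictly increasing in \code{k} and strictly decreasing in
#' \code{d}, so faster intrinsic growth and a sharper sigmoid both map
#' monotonically onto the rate.
#'
#' @param k growth rate constant (1/day), or a \code{richards_fit} object.
#' @param d shape parameter (> 1); ignored when \code{k} is a fit object.
#' @return Normalized average growth rate (1/day).
#' @examples
#' normalized_growth_rate(k = 0.6, d = 2)  # 0.1
#' @export
normalized_growth_rate <- function(k, d) {
  if (inherits(k, "richards_fit")) {
    p <- coef(k)
    return(unname(p["k"] / (2 * (p["d"] + 1))))
  }
  if (!is.numeric(k) || !is.numeric(d)) stop("'k' and 'd' must be numeric")
  if (any(k <= 0)) stop("'k' must be > 0")
  if (any(d <= 1)) stop("'d' must be > 1")
  k / (2 * (d + 1))
}

# Starting values: asymptote from the smoothed maximum, inflection from the
# half-maximum crossing, k from the early-phase log-linear slope, d at the
# logistic special case.
richards_start <- function(x, y) {
  ys <- if (length(y) >= 5) stats::runmed(y, 3) else y
  a0 <- max(ys)
  if (a0 <= 0) a0 <- max(y, 1e-3)
  half <- a0 / 2
  above <- which(ys >= half)
  xc0 <- if (length(above)) x[above[1]] else stats::median(x)
  early <- which(ys > 0.05 * a0 & ys < 0.8 * a0)
  k0 <- 0.5
  if (length(early) >= 2) {
    sl <- stats::coef(stats::lm(log(pmax(ys[early], 1e-6)) ~ x[early]))[2]
    if (is.finite(sl) && sl > 0) k0 <- min(max(sl, 0.05), 5)
  }
  c(a = a0, k = k0, d = 2, xc = xc0)
}

#' Fit the Richards growth model to a blank-subtracted OD series
#'
#' Least-squares fit of the four-parameter Richards curve to one well's
#' blank-subtracted optical-density time series, by bounded
#' Levenberg-Marquardt. Bounds keep the solver on the sigmoid branch
#' (\code{d > 1}) and away from the \code{d -> 1} singularity:
#' \code{a} in (0, 2 max OD], \code{k} in (0, 10], \code{d} in (1, 20],
#' \code{xc} in [min(x) - 5, max(x) + 5].
#'
#' After fitting, the well is called growth / no-growth by
#' \code{\link{call_growth}}: growth requires both a maximum blank-subtracted
#' OD at or above \code{threshold_od} and a converged fit with
#' \eqn{R^2 \ge} \code{threshold_r2}. No-growth wells are recorded with rate
#' 0. When the solver cannot converge the fit is flagged and the growth call
#' falls back to the OD threshold alone.
#'
#' @param x time points (days) or a formula \code{od ~ day}.
#' @param y OD readings (ignored for the formula method).
#' @param data data frame for the formula method.
#' @param threshold_od minimum peak blank-subtracted OD for a growth call
#'   (absorbance units; default 0.05).
#' @param threshold_r2 minimum coefficient of determination for a growth call
#'   (default 0.7).
#' @param max_iter maximum solver iterations.
#' @param start optional named vector \code{c(a, k, d, xc)} of starting
#'   values; data-driven defaults otherwise.
#' @param ... passed between methods.
#' @return An object of class \code{richards_fit} with components
#'   \code{params} (named vector a, k, d, xc), \code{rate} (normalized
#'   average growth rate, 0 for no-growth wells), \code{rss}, \code{r2},
#'   \code{converged}, \code{growth}, \code{x}, \code{y}, \code{fitted},
#'   \code{n}.
#' @examples
#' x <- 0:29
#' y <- richards(x, a = 0.8, k = 0.5, d = 3, xc = 12)
#' fit <- richards_fit(x, y)
#' coef(fit)
#' normalized_growth_rate(fit)
#' @export
richards_fit <- function(x, ...) UseMethod("richards_fit")

#' @rdname richards_fit
#' @export
richards_fit.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  richards_fit.default(mf[[2L]], mf[[1L]], ...)
}

#' @rdname richards_fit
#' @export
richards_fit.default <- function(x, y, threshold_od = 0.05, threshold_r2 = 0.7,
                                 max_iter = 200, start = NULL, ...) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y)))) stop("non-finite values in series")
  n <- length(x)
  if (n < 5) stop("insufficient data: at least 5 time points are required, got ", n)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]

  maxod <- max(y)
  lower <- c(a = 1e-6, k = 1e-6, d = 1 + 1e-6, xc = min(x) - 5)
  upper <- c(a = max(2 * maxod, 1e-3), k = 10, d = 20, xc = max(x) + 5)
  if (is.null(start)) start <- richards_start(x, y)
  start <- pmin(pmax(start[c("a", "k", "d", "xc")], lower), upper)

  params <- c(a = NA_real_, k = NA_real_, d = NA_real_, xc = NA_real_)
  converged <- FALSE
  rss <- sum((y - mean(y))^2)
  fitted_y <- rep(mean(y), n)

  # multi-start: the data-driven start plus a few coarse fallbacks; keep the
  # best converged least-squares solution
  starts <- list(start,
                 c(a = max(maxod, 1e-3), k = 0.3, d = 3, xc = stats::median(x)),
                 c(a = max(maxod, 1e-3), k = 1, d = 2, xc = min(x) + diff(range(x)) / 3))
  best_rss <- Inf
  for (s0 in starts) {
    s0 <- pmin(pmax(s0[c("a", "k", "d", "xc")], lower), upper)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ a * (1 + (d - 1) * exp(-k * (x - xc)))^(1 / (1 - d)),
        start = as.list(s0), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-12,
                                             ptol = 1e-12)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    this_rss <- sum(stats::residuals(fit)^2)
    if (this_rss < best_rss) {
      best_rss <- this_rss
      params <- stats::coef(fit)[c("a", "k", "d", "xc")]
      fitted_y <- as.numeric(stats::fitted(fit))
      rss <- this_rss
      converged <- isTRUE(fit$convInfo$isConv) || fit$convInfo$stopCode %in% 1:3
    }
  }

  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0

  out <- structure(
    list(params = params, rate = 0, rss = rss, r2 = r2,
         converged = converged, growth = NA, x = x, y = y,
         fitted = fitted_y, n = n,
         thresholds = c(od = threshold_od, r2 = threshold_r2)),
    class = "richards_fit"
  )
  out$growth <- call_growth(out, threshold_od = threshold_od,
                            threshold_r2 = threshold_r2)
  if (out$growth && !anyNA(params)) {
    out$rate <- unname(params["k"] / (2 * (params["d"] + 1)))
  }
  out
}

#' Decide growth versus no-growth for a fitted well
#'
#' A well is called growing when its peak blank-subtracted OD reaches
#' \code{threshold_od} (boundary inclusive) \emph{and} the Richards fit
#' converged with a coefficient of determination of at least
#' \code{threshold_r2}. A flat or noise-only trace fails the OD gate; a trace
#' that reaches the OD gate but is not sigmoid-shaped fails the fit-quality
#' gate. If the solver did not converge the call falls back to the OD
#' threshold alone, so strong growth is not discarded on solver failure.
#'
#' @param fit a \code{richards_fit} object.
#' @param threshold_od minimum peak OD (absorbance units).
#' @param threshold_r2 minimum coefficient of determination.
#' @return Logical growth flag.
#' @export
call_growth <- function(fit, threshold_od = 0.05, threshold_r2 = 0.7) {
  stopifnot(inherits(fit, "richards_fit"))
  od_ok <- max(fit$y) >= threshold_od
  if (!fit$converged) return(od_ok)
  od_ok && fit$r2 >= threshold_r2
}

#' @export
coef.richards_fit <- function(object, ...) object$params

#' @export
fitted.richards_fit <- function(object, ...) object$fitted

#' @export
residuals.richards_fit <- function(object, ...) object$y - object$fitted

#' @export
predict.richards_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- if (is.data.frame(newdata)) newdata[[1L]] else newdata
  p <- object$params
  if (anyNA(p)) stop("cannot predict from a fit that did not converge")
  richards(x, p["a"], p["k"], p["d"], p["xc"])
}

#' @export
print.richards_fit <- function(x, digits = 4, ...) {
  cat("Richards growth-curve fit (", x$n, " points)\n", sep = "")
  if (!anyNA(x$params)) {
    print(round(x$params, digits))
  } else {
    cat("  <solver failed>\n")
  }
  cat("rate: ", format(x$rate, digits = digits),
      " 1/day   R2: ", format(x$r2, digits = digits),
      "   growth: ", x$growth,
      if (!x$converged) "   (not converged)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.richards_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.richards_fit")
}

#' @export
print.summary.richards_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("rss: ", format(f$rss, digits = 6),
      "   residual sd: ", format(sqrt(f$rss / max(f$n - 4, 1)), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.richards_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "day", ylab = "blank-subtracted OD630",
                 main = "Richards growth-curve fit", ...)
  if (!anyNA(x$params)) {
    xx <- seq(min(x$x), max(x$x), length.out = 200)
    graphics::lines(xx, predict(x, xx), col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Simulate replicate series from a fitted Richards curve
#'
#' Draws new OD series from the fitted curve plus Gaussian noise at the
#' residual standard deviation, truncated at zero (absorbance cannot be
#' negative).
#'
#' @param object a converged \code{richards_fit}.
#' @param nsim number of simulated series.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with one column per simulated series and
#'   row-per-time-point, with attribute \code{"x"} carrying the time grid.
#' @export
simulate.richards_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (anyNA(object$params)) stop("cannot simulate from a fit that did not converge")
  sd <- sqrt(object$rss / max(object$n - 4, 1))
  mu <- object$fitted
  out <- as.data.frame(replicate(nsim, pmax(mu + stats::rnorm(length(mu), 0, sd), 0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "x") <- object$x
  out
}
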