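#' Fit an exponential-decay model y = a exp(-b x) + c
#'
#' Central model of the package: the relationship between the citrated rapid
#' TEG reaction time (CRT-R, minutes) and a final clot-strength parameter
#' (maximum amplitude, mm) is modelled as \deqn{y = a e^{-b x} + c} where
#' \code{a} is the initial value above (or below, if \code{a < 0}) the
#' asymptote, \code{b > 0} is the decay rate per minute, and \code{c} is the
#' asymptotic value. Parameters are estimated by nonlinear least squares,
#' with the decay rate searched on the log scale so it stays positive;
#' \code{a} and \code{c} are unconstrained (increasing curves have
#' \code{a < 0}).
#'
#' When \code{start} is not given, starting values come from a shape
#' heuristic: the sign of the Pearson correlation decides whether the curve is
#' treated as decreasing or increasing; \code{c} starts at the corresponding
#' extreme of \code{y}, \code{a} at the signed \code{y}-range, and \code{b} at
#' the reciprocal of the \code{x}-range.
#'
#' Estimation uses variable projection: for fixed \code{b} the model is
#' linear in \code{(a, c)}, so those are solved in closed form and the
#' profiled sum of squares is minimised over \code{log b} by a coarse
#' bracketing grid followed by Brent refinement. This is deterministic given
#' the data and starting values, and robust on weakly identified fits (a
#' nearly flat asymptote under heavy noise), where general-purpose
#' Gauss-Newton steps can stall.
#'
#' @param formula a two-sided formula, outcome ~ predictor.
#' @param data a data.frame containing the variables in \code{formula};
#'   rows with a missing value in either variable are dropped.
#' @param start optional named numeric vector or list with elements
#'   \code{a}, \code{b}, \code{c} (\code{b > 0}); only \code{b} steers the
#'   optimizer (it centres the profiled search), \code{a} and \code{c} are
#'   profiled out exactly.
#' @param control a list from [expdecay_control()]: search width, grid
#'   resolution and convergence tolerance of the profiled optimizer.
#'
#' @return an object of class \code{"expdecay"} with components
#'   \code{coefficients} (named vector a, b, c), \code{fitted.values},
#'   \code{residuals}, \code{sigma} (residual standard error),
#'   \code{diagnostics} (Pearson \code{r}, \code{abs_r}, \code{p_value},
#'   \code{r2}, \code{mae}, \code{rmse}, \code{n}), \code{data} (the complete
#'   pairs used), \code{start} (initial values used) and \code{call}.
#'   On optimizer failure a condition of class \code{"tegcut_fit_failure"} is
#'   signalled; its \code{best} field carries the best parameters seen.
#'
#' @examples
#' d <- data.frame(x = seq(0.3, 5.5, length.out = 40))
#' d$y <- 29.9054 * exp(-0.7345 * d$x) + 0.3548
#' fit <- expdecay(y ~ x, d)
#' coef(fit)
#' invert_exp_decay(fit, 12)
#' @seealso [invert_exp_decay()], [bootstrap_cutoff()], [fit_linear()]
#' @export
expdecay <- function(formula, data, start = NULL, control = expdecay_control()) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  if (ncol(mf) != 2L)
    stop("formula must have exactly one outcome and one predictor")
  y <- mf[[1L]]
  x <- mf[[2L]]
  fit <- expdecay_fit(x, y, start = start, control = control)
  fit$call <- cl
  fit$formula <- formula
  fit
}

#' Optimizer settings for [expdecay()]
#'
#' The profiled sum of squares is scanned over \code{log b} on a grid of
#' \code{n_grid} points spanning \code{log(b_start)} plus/minus \code{span}
#' (so the default covers four hundred-fold deviations of the decay rate in
#' either direction), then refined by Brent search in the bracketing cell.
#'
#' @param span half-width of the search window on the log decay-rate scale.
#' @param n_grid number of bracketing grid points.
#' @param tol absolute convergence tolerance of the Brent refinement on
#'   \code{log b}.
#' @return a list passed to the optimizer.
#' @export
expdecay_control <- function(span = 6, n_grid = 61, tol = 1e-10) {
  stopifnot(span > 0, n_grid >= 5, tol > 0)
  list(span = span, n_grid = as.integer(n_grid), tol = tol)
}

# workhorse on bare vectors (bootstrap refits call this directly)
expdecay_fit <- function(x, y, start = NULL, control = expdecay_control()) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L || length(unique(x)) < 4L)
    stop("need at least 4 distinct predictor values")
  if (is.null(start)) start <- expdecay_start(x, y)
  start <- unlist(start)[c("a", "b", "c")]
  if (anyNA(start) || start[["b"]] <= 0)
    stop("start must supply finite a, c and b > 0")

  s_y <- sum(y)
  # (a, c) minimising the SSE for a fixed decay rate, by normal equations;
  # a degenerate regressor (b so extreme that exp(-b x) is constant)
  # collapses to the intercept-only fit
  profile_ac <- function(b) {
    e <- exp(-b * x)
    s_e <- sum(e); s_ee <- sum(e * e); s_ye <- sum(y * e)
    den <- n * s_ee - s_e * s_e
    if (!is.finite(den) || den <= .Machine$double.eps * n * max(s_ee, 1)) {
      cbar <- s_y / n
      return(list(a = 0, c = cbar, sse = sum((y - cbar)^2)))
    }
    a <- (n * s_ye - s_e * s_y) / den
    cc <- (s_y - a * s_e) / n
    list(a = a, c = cc, sse = sum((y - a * e - cc)^2))
  }
  sse_of <- function(lb) profile_ac(exp(lb))$sse

  lb0 <- log(start[["b"]])
  grid <- seq(lb0 - control$span, lb0 + control$span,
              length.out = control$n_grid)
  ss <- vapply(grid, sse_of, numeric(1))
  if (all(!is.finite(ss))) {
    cond <- structure(
      class = c("tegcut_fit_failure", "error", "condition"),
      list(message = "exponential-decay fit failed: profiled SSE not finite anywhere in the search window",
           call = sys.call(-1L), best = start, best_sse = Inf))
    stop(cond)
  }
  i <- which.min(ss)
  opt <- stats::optimize(sse_of,
                         c(grid[max(1L, i - 1L)],
                           grid[min(control$n_grid, i + 1L)]),
                         tol = control$tol)
  lb <- if (is.finite(opt$objective) && opt$objective <= ss[i])
    opt$minimum else grid[i]
  b <- exp(lb)
  sol <- profile_ac(b)
  cf <- c(a = sol$a, b = b, c = sol$c)
  fitted <- cf[["a"]] * exp(-cf[["b"]] * x) + cf[["c"]]
  resd <- y - fitted
  diag <- fit_diagnostics(x, y, fitted)
  structure(list(coefficients = cf,
                 fitted.values = fitted,
                 residuals = resd,
                 sigma = sqrt(sum(resd^2) / max(n - 3L, 1L)),
                 diagnostics = diag,
                 data = list(x = x, y = y),
                 start = start,
                 call = match.call()),
            class = "expdecay")
}

# shape heuristic for starting values; robust to both decreasing
# (a > 0) and increasing (a < 0) curves
expdecay_start <- function(x, y) {
  r <- suppressWarnings(stats::cor(x, y))
  decreasing <- !is.finite(r) || r <= 0
  rng <- diff(range(y))
  if (rng == 0) rng <- max(abs(y[1L]), 1)
  c(a = if (decreasing) rng else -rng,
    b = 1 / max(diff(range(x)), .Machine$double.eps),
    c = if (decreasing) min(y) else max(y))
}

#' @export
coef.expdecay <- function(object, ...) object$coefficients

#' @export
fitted.expdecay <- function(object, ...) object$fitted.values

#' @export
residuals.expdecay <- function(object, ...) object$residuals

#' Predict from a fitted exponential-decay model
#'
#' @param object an \code{"expdecay"} fit.
#' @param newdata numeric vector of predictor values, or a data.frame
#'   containing the predictor variable of the model formula. Missing:
#'   fitted values are returned.
#' @param ... unused.
#' @return numeric vector of predicted outcome values.
#' @export
predict.expdecay <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  x <- if (is.data.frame(newdata)) {
    v <- all.vars(object$formula)[2L]
    if (!v %in% names(newdata)) stop("newdata lacks predictor '", v, "'")
    newdata[[v]]
  } else as.numeric(newdata)
  cf <- object$coefficients
  cf[["a"]] * exp(-cf[["b"]] * x) + cf[["c"]]
}

#' @export
print.expdecay <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  cat("Exponential-decay fit: y = a*exp(-b*x) + c\n")
  cat(sprintf("  a = %.*f, b = %.*f, c = %.*f  (n = %d)\n",
              digits, cf[["a"]], digits, cf[["b"]], digits, cf[["c"]],
              x$diagnostics$n))
  invisible(x)
}

#' @export
summary.expdecay <- function(object, ...) {
  structure(list(coefficients = object$coefficients,
                 diagnostics = object$diagnostics,
                 sigma = object$sigma,
                 call = object$call),
            class = "summary.expdecay")
}

#' @export
print.summary.expdecay <- function(x, digits = 4, ...) {
  cat("Exponential-decay model  y = a*exp(-b*x) + c\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(round(x$coefficients, digits))
  d <- x$diagnostics
  cat(sprintf(
    "\nn = %d,  r = %.4f (|r| = %.4f),  p = %.3g\nR2 = %.4f,  MAE = %.4f,  RMSE = %.4f,  sigma = %.4f\n",
    d$n, d$r, d$abs_r, d$p_value, d$r2, d$mae, d$rmse, x$sigma))
  invisible(x)
}

#' Scatter plot with fitted decay curve
#'
#' @param x an \code{"expdecay"} fit.
#' @param n_grid number of grid points for the curve.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data.frame of the plotted curve (grid x, fitted y).
#' @export
plot.expdecay <- function(x, n_grid = 200, ...) {
  d <- x$data
  graphics::plot(d$x, d$y, xlab = "predictor", ylab = "outcome", ...)
  g <- seq(min(d$x), max(d$x), length.out = n_grid)
  fy <- predict(x, g)
  graphics::lines(g, fy, lwd = 2)
  invisible(data.frame(x = g, y = fy))
}

#' Simulate outcomes from a fitted exponential-decay model
#'
#' Draws Gaussian residuals with the fit's residual standard error around the
#' fitted mean curve, at the original predictor values.
#'
#' @param object an \code{"expdecay"} fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed (global RNG state is restored on exit).
#' @param ... unused.
#' @return data.frame with \code{nsim} columns \code{sim_1, ...}.
#' @export
simulate.expdecay <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) local_seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(
    replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma),
              simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  out
}

# set the RNG seed for the calling frame only, restoring global state on exit
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  expr <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(seed)
}
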