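#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between paired values, with the two-sided
#' p-value from \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of
#' freedom. Both the signed coefficient and its magnitude are returned, since
#' correlation strength is commonly reported as |r| while the direction of the
#' CRT-R/MA relationships is negative.
#'
#' @param x,y numeric vectors; pairs with a missing value are dropped.
#' @return list with \code{r}, \code{abs_r}, \code{p_value}, \code{n}.
#' @export
pearson_correlation <- function(x, y) {
  xn <- deparse1(substitute(x)); yn <- deparse1(substitute(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("undefined correlation: '", xn, "' has zero variance")
  if (stats::sd(y) == 0) stop("undefined correlation: '", yn, "' has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), abs_r = abs(unname(ct$estimate)),
       p_value = ct$p.value, n = n)
}

#' Ordinary least-squares line with fit diagnostics
#'
#' Simple linear regression of \code{y} on \code{x}, used for the CRT-R vs
#' TEG-ACT relationship (all other channel relationships use [expdecay()]).
#'
#' @param x,y numeric vectors; pairs with a missing value are dropped.
#' @return object of class \code{"teg_linear"}: \code{slope},
#'   \code{intercept}, \code{diagnostics} (as in [goodness_of_fit()]),
#'   \code{fit} (the underlying \code{lm}).
#' @export
fit_linear <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop("degenerate design: need at least 2 distinct x values")
  fit <- stats::lm(y ~ x)
  fitted <- unname(stats::fitted(fit))
  diag <- fit_diagnostics(x, y, fitted)
  structure(list(slope = unname(stats::coef(fit))[2L],
                 intercept = unname(stats::coef(fit))[1L],
                 diagnostics = diag, fit = fit,
                 data = list(x = x, y = y)),
            class = "teg_linear")
}

#' @export
coef.teg_linear <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.teg_linear <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(stats::fitted(object$fit)))
  x <- if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  object$intercept + object$slope * x
}

#' @export
print.teg_linear <- function(x, digits = 4, ...) {
  cat(sprintf("Linear fit: y = %.*f * x + %.*f  (n = %d, R2 = %.4f)\n",
              digits, x$slope, digits, x$intercept,
              x$diagnostics$n, x$diagnostics$r2))
  invisible(x)
}

#' Goodness-of-fit diagnostics for a fitted channel model
#'
#' Computes Pearson r (signed and absolute, with two-sided p-value),
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, mean absolute error and root mean
#' square error of a model's predictions against observed outcomes.
#' When the outcome has zero variance, \eqn{R^2} is reported as 0 with a
#' warning (documented convention).
#'
#' @param model an \code{"expdecay"} fit, a \code{"teg_linear"} fit, or a list
#'   with elements \code{a}, \code{b}, \code{c} of a decay curve.
#' @param x,y numeric vectors of predictor and observed outcome.
#' @return list with \code{r}, \code{abs_r}, \code{p_value}, \code{r2},
#'   \code{mae}, \code{rmse}, \code{n}.
#' @export
goodness_of_fit <- function(model, x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  yhat <- if (inherits(model, "expdecay") || inherits(model, "teg_linear")) {
    predict(model, x)
  } else if (is.list(model) && all(c("a", "b", "c") %in% names(model))) {
    model$a * exp(-model$b * x) + model$c
  } else stop("unsupported model type")
  fit_diagnostics(x, y, yhat)
}

# shared diagnostics core; r/p only when correlation is defined
fit_diagnostics <- function(x, y, yhat) {
  n <- length(y)
  res <- y - yhat
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("outcome has zero variance; R2 reported as 0 by convention")
    r2 <- 0
  } else r2 <- 1 - ss_res / ss_tot
  r <- NA_real_; p <- NA_real_
  if (n >= 3L && stats::sd(x) > 0 && stats::sd(y) > 0) {
    ct <- stats::cor.test(x, y)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(r = r, abs_r = abs(r), p_value = p, r2 = r2,
       mae = mean(abs(res)), rmse = sqrt(mean(res^2)), n = n)
}
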