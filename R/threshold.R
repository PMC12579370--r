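#' Invert an exponential-decay curve at an outcome target
#'
#' Solves \eqn{a e^{-bx} + c = y} for \eqn{x}: the CRT-R value at which the
#' fitted curve predicts the clinical MA target. The unique solution is
#' \deqn{x = -\frac{1}{b}\,\ln\!\left(\frac{y - c}{a}\right),}
#' defined only when \eqn{(y - c)/a > 0} (the target lies strictly between the
#' asymptote and the curve's unbounded side).
#'
#' @param model an \code{"expdecay"} fit or a list/vector with \code{a},
#'   \code{b}, \code{c}.
#' @param y_target numeric vector of outcome targets (e.g. MA in mm).
#' @return numeric vector of predictor values (minutes). If any target has no
#'   solution, a condition of class \code{"tegcut_no_solution"} is signalled
#'   (distinct from a fit failure, so bootstrap accounting can tell them
#'   apart).
#' @examples
#' invert_exp_decay(list(a = 29.9054, b = 0.7345, c = 0.3548), 12)
#' @export
invert_exp_decay <- function(model, y_target) {
  cf <- if (inherits(model, "expdecay")) as.list(coef(model)) else as.list(model)
  a <- cf$a; b <- cf$b; c <- cf$c
  if (is.null(a) || is.null(b) || is.null(c) || b <= 0)
    stop("model must supply a, c and b > 0")
  ratio <- (y_target - c) / a
  if (any(!is.finite(ratio) | ratio <= 0)) {
    bad <- y_target[!is.finite(ratio) | ratio <= 0]
    cond <- structure(
      class = c("tegcut_no_solution", "error", "condition"),
      list(message = paste0("no solution: target(s) ",
                            paste(format(bad), collapse = ", "),
                            " outside the curve's range (asymptote c = ",
                            format(c), ")"),
           call = sys.call(-1L)))
    stop(cond)
  }
  -log(ratio) / b
}

#' Bootstrap percentile distribution of a model-inverted cutoff
#'
#' Resamples measurement pairs with replacement, refits the exponential-decay
#' model on each resample (initialised from the full-sample fit), inverts it
#' at the MA target, and summarises the distribution of cutoffs by its 2.5th,
#' 25th, 50th, 75th and 97.5th percentiles (linear interpolation between order
#' statistics). Resamples whose fit fails or whose curve cannot reach the
#' target are discarded and counted; if fewer than \code{min_success} of the
#' requested resamples succeed, a condition of class \code{"tegcut_unstable"}
#' carrying the partial cutoff distribution is signalled.
#'
#' @param x predictor values (CRT-R, minutes).
#' @param y outcome values (MA, mm), paired with \code{x}.
#' @param y_target MA target to invert at (scalar).
#' @param n_boot number of bootstrap resamples.
#' @param seed optional integer seed; global RNG state is restored on exit.
#'   When \code{NULL} the current RNG stream is used.
#' @param min_success minimum tolerated fraction of successful resamples.
#' @param control optimizer settings, see [expdecay_control()].
#' @return object of class \code{"cutoff_estimate"}: \code{y_target},
#'   \code{point} (full-sample-fit inversion), \code{boot_median},
#'   \code{boot_q25}, \code{boot_q75}, \code{boot_ci_lo}, \code{boot_ci_hi}
#'   (2.5/97.5 percentiles), \code{n_boot_requested},
#'   \code{n_boot_succeeded}, \code{fit} (full-sample \code{"expdecay"}) and
#'   \code{cutoffs} (the successful bootstrap cutoffs).
#' @export
bootstrap_cutoff <- function(x, y, y_target, n_boot = 1000, seed = NULL,
                             min_success = 0.9,
                             control = expdecay_control()) {
  stopifnot(n_boot >= 1, length(y_target) == 1L, is.finite(y_target))
  if (!is.null(seed)) local_seed(seed)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)

  full <- expdecay_fit(x, y, control = control)
  point <- invert_exp_decay(full, y_target)
  start <- coef(full)

  cutoffs <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cutoffs[i] <- tryCatch(
      invert_exp_decay(
        expdecay_fit(x[idx], y[idx], start = start, control = control),
        y_target),
      tegcut_fit_failure = function(e) NA_real_,
      tegcut_no_solution = function(e) NA_real_)
  }
  ok <- cutoffs[!is.na(cutoffs)]
  if (length(ok) < min_success * n_boot) {
    cond <- structure(
      class = c("tegcut_unstable", "error", "condition"),
      list(message = sprintf(
        "bootstrap unstable: only %d of %d resamples succeeded (< %.0f%%)",
        length(ok), n_boot, 100 * min_success),
        call = sys.call(-1L), cutoffs = ok))
    stop(cond)
  }
  q <- stats::quantile(ok, c(0.025, 0.25, 0.5, 0.75, 0.975),
                       names = FALSE, type = 7)
  structure(list(y_target = y_target, point = point,
                 boot_median = q[3L], boot_q25 = q[2L], boot_q75 = q[4L],
                 boot_ci_lo = q[1L], boot_ci_hi = q[5L],
                 n_boot_requested = as.integer(n_boot),
                 n_boot_succeeded = length(ok),
                 fit = full, cutoffs = ok),
            class = "cutoff_estimate")
}

#' @export
print.cutoff_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("CRT-R cutoff for outcome target %.4g\n", x$y_target))
  cat(sprintf("  point estimate (full fit): %.*f min\n", digits, x$point))
  cat(sprintf("  bootstrap median: %.*f  IQR: %.*f-%.*f  95%% CI: %.*f-%.*f\n",
              digits, x$boot_median, digits, x$boot_q25, digits, x$boot_q75,
              digits, x$boot_ci_lo, digits, x$boot_ci_hi))
  cat(sprintf("  resamples: %d / %d succeeded\n",
              x$n_boot_succeeded, x$n_boot_requested))
  invisible(x)
}

#' Diagnostic performance of a CRT-R cutoff
#'
#' Classifies each pair with predicted-positive = CRT-R strictly above the
#' cutoff and actual-positive = MA strictly below the target, and tabulates
#' the 2x2 confusion counts and the derived ratios. A ratio with zero
#' denominator is returned as \code{NA} and listed in \code{undefined};
#' the remaining metrics are still computed.
#'
#' @param crt_r CRT-R values (minutes).
#' @param cutoff CRT-R cutoff (minutes); ties (\code{crt_r == cutoff}) are
#'   predicted negative.
#' @param ma outcome MA values (mm), paired with \code{crt_r}.
#' @param y_target MA target defining actual-positive (\code{ma < y_target}).
#' @return object of class \code{"confusion_metrics"}: \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}, \code{sensitivity}, \code{specificity}, \code{ppv},
#'   \code{npv}, \code{accuracy}, \code{n}, \code{undefined} (character vector
#'   of metrics with zero denominator).
#' @export
classify_at_cutoff <- function(crt_r, cutoff, ma, y_target) {
  stopifnot(length(cutoff) == 1L, is.finite(cutoff),
            length(y_target) == 1L, is.finite(y_target))
  keep <- is.finite(crt_r) & is.finite(ma)
  crt_r <- crt_r[keep]; ma <- ma[keep]
  pred <- crt_r > cutoff
  actual <- ma < y_target
  tp <- sum(pred & actual); fp <- sum(pred & !actual)
  tn <- sum(!pred & !actual); fn <- sum(!pred & actual)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(tp = tp, fp = fp, tn = tn, fn = fn,
            sensitivity = ratio(tp, tp + fn),
            specificity = ratio(tn, tn + fp),
            ppv = ratio(tp, tp + fp),
            npv = ratio(tn, tn + fn),
            accuracy = ratio(tp + tn, tp + fp + tn + fn),
            n = tp + fp + tn + fn)
  m$undefined <- names(which(vapply(
    m[c("sensitivity", "specificity", "ppv", "npv", "accuracy")],
    is.na, logical(1))))
  structure(m, class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Confusion at cutoff (n = %d): TP %d, FP %d, TN %d, FN %d\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  pct <- function(v) if (is.na(v)) "undef" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("  sensitivity %s, specificity %s, PPV %s, NPV %s, accuracy %s\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$ppv),
              pct(x$npv), pct(x$accuracy)))
  invisible(x)
}

# linear CRT-R / TEG-ACT conversion (device-reported activated clotting time)
.act_slope <- 0.0107   # min per s
.act_intercept <- -0.5397  # min
.act_range <- c(60, 199)   # s, observed plausible range

#' Convert between TEG-ACT (seconds) and CRT-R (minutes)
#'
#' The device-derived activated clotting time (TEG-ACT, seconds) and the
#' reaction time CRT-R (minutes) are linearly related:
#' \deqn{CRT\text{-}R = 0.0107 \cdot ACT - 0.5397.}
#' \code{act_to_crt_r} applies this map; \code{crt_r_to_act} is its exact
#' algebraic inverse. Inputs outside the plausible ACT range 60-199 s trigger
#' a warning, not a failure.
#'
#' @param act TEG-ACT values in seconds.
#' @param crt_r CRT-R values in minutes.
#' @return converted values (minutes for \code{act_to_crt_r}, seconds for
#'   \code{crt_r_to_act}).
#' @examples
#' act_to_crt_r(128)  # 0.8299 min, ~0.83
#' crt_r_to_act(act_to_crt_r(105))  # exact roundtrip
#' @export
act_to_crt_r <- function(act) {
  if (any(act < .act_range[1L] | act > .act_range[2L], na.rm = TRUE))
    warning("TEG-ACT outside the plausible range 60-199 s")
  .act_slope * act + .act_intercept
}

#' @rdname act_to_crt_r
#' @export
crt_r_to_act <- function(crt_r) {
  act <- (crt_r - .act_intercept) / .act_slope
  if (any(act < .act_range[1L] | act > .act_range[2L], na.rm = TRUE))
    warning("converted TEG-ACT outside the plausible range 60-199 s")
  act
}
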