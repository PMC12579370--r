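#' Configuration of a full analysis run
#'
#' Bundles everything [run_analysis()] needs: the input (a CSV path or a
#' generator [cohort_config()]), which channel relationships to model, the
#' clinical MA targets at which cutoffs are derived, the bootstrap size and
#' the seed. The default analyses mirror the study: exponential decay for the
#' three MA channels and CKH-R, a linear conversion model for TEG-ACT (with
#' CRT-R as the response, the orientation of the reported conversion
#' equation), and cutoffs at CRT-MA = 48 mm and CFF-MA = 12 mm.
#'
#' @param input a path to a cohort CSV, or a [cohort_config()] to simulate
#'   from.
#' @param analyses named character vector mapping outcome column to model kind
#'   (\code{"exp_decay"} or \code{"linear"}).
#' @param ma_targets named numeric vector mapping outcome column to the MA
#'   target (mm) at which a CRT-R cutoff is derived.
#' @param n_boot bootstrap resamples per cutoff.
#' @param seed integer seed for the run's RNG stream (bootstrap resampling;
#'   generation uses the cohort config's own seed).
#' @param max_crt_r exclusion threshold (min), see [apply_exclusions()].
#' @param out_dir optional directory; when set, [run_analysis()] writes
#'   \code{report.json}, one \code{curve_<outcome>.csv} per analysis and
#'   \code{cutoffs.csv} there.
#' @return a validated list of class \code{"run_config"}.
#' @export
run_config <- function(input = cohort_config(),
                       analyses = c(crt_ma_mm = "exp_decay",
                                    ckh_r_min = "exp_decay",
                                    ckh_ma_mm = "exp_decay",
                                    cff_ma_mm = "exp_decay",
                                    teg_act_s = "linear"),
                       ma_targets = c(crt_ma_mm = 48, cff_ma_mm = 12),
                       n_boot = 1000, seed = 1L, max_crt_r = 5.5,
                       out_dir = NULL) {
  if (!inherits(input, "cohort_config") &&
      !(is.character(input) && length(input) == 1L))
    stop("input must be a file path or a cohort_config")
  known <- teg_measurement_columns()
  if (!all(names(analyses) %in% known))
    stop("unknown analysis column(s): ",
         paste(setdiff(names(analyses), known), collapse = ", "))
  if (!all(analyses %in% c("exp_decay", "linear")))
    stop("analysis kinds must be 'exp_decay' or 'linear'")
  if (!all(names(ma_targets) %in% names(analyses)))
    stop("every ma_target must name an analysed channel")
  if (any(ma_targets <= 0)) stop("ma_targets must be positive")
  stopifnot(n_boot >= 1, max_crt_r > 0)
  structure(list(input = input, analyses = analyses,
                 ma_targets = ma_targets, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), max_crt_r = max_crt_r,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: load or simulate the cohort; apply the exclusion
#' rules (completeness across all six measurements, then CRT-R range);
#' summarise the retained cohort; for each configured relationship compute the
#' Pearson correlation and fit the mean-structure model with goodness-of-fit
#' diagnostics; for each MA target derive the CRT-R cutoff by bootstrap and
#' evaluate it as a classifier on the retained cohort (using the bootstrap
#' median as the operative cutoff). Identical configuration and seed give an
#' identical report.
#'
#' @param config a [run_config()].
#' @return object of class \code{"teg_analysis"}: \code{exclusions}
#'   (\code{"exclusion_report"}), \code{summary} (per-channel statistics),
#'   \code{fits} (per-outcome list: kind, params, diagnostics),
#'   \code{cutoffs} (per-target list: \code{"cutoff_estimate"} and
#'   \code{"confusion_metrics"}), \code{provenance}. If \code{out_dir} is set,
#'   JSON and CSV artifacts are written there as a side effect.
#' @examples
#' cfg <- run_config(input = cohort_config(n_records = 400, seed = 3),
#'                   n_boot = 50, seed = 3)
#' res <- run_analysis(cfg)
#' print(res)
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  local_seed(config$seed)

  data <- if (inherits(config$input, "cohort_config"))
    simulate_cohort(config$input) else read_teg_csv(config$input)

  excl <- apply_exclusions(data, max_crt_r = config$max_crt_r)
  d <- excl$data
  if (!nrow(d)) stop("stage preprocess: no records survive the exclusion rules")
  cohort <- summarize_cohort(d)

  fits <- list()
  for (outcome in names(config$analyses)) {
    kind <- config$analyses[[outcome]]
    fits[[outcome]] <- tryCatch(
      analyse_channel(d, outcome, kind),
      error = function(e) stop("stage association (", outcome, "): ",
                               conditionMessage(e), call. = FALSE))
  }

  cutoffs <- list()
  for (outcome in names(config$ma_targets)) {
    target <- config$ma_targets[[outcome]]
    cutoffs[[outcome]] <- tryCatch({
      est <- bootstrap_cutoff(d$crt_r_min, d[[outcome]], target,
                              n_boot = config$n_boot)
      perf <- classify_at_cutoff(d$crt_r_min, est$boot_median,
                                 d[[outcome]], target)
      list(estimate = est, performance = perf)
    }, error = function(e) stop("stage threshold (", outcome, " = ", target,
                                "): ", conditionMessage(e), call. = FALSE))
  }

  res <- structure(list(exclusions = excl$report,
                        summary = cohort,
                        fits = fits,
                        cutoffs = cutoffs,
                        provenance = list(
                          config = config_echo(config),
                          seed = config$seed,
                          package_version = as.character(
                            utils::packageVersion("tegcut")))),
                   class = "teg_analysis")
  if (!is.null(config$out_dir)) write_analysis_outputs(res, config)
  res
}

# one channel relationship: correlation + mean-structure fit + diagnostics
analyse_channel <- function(d, outcome, kind) {
  if (kind == "linear") {
    # conversion-model orientation: CRT-R is the response
    x <- d[[outcome]]; y <- d$crt_r_min
  } else {
    x <- d$crt_r_min; y <- d[[outcome]]
  }
  fit <- if (kind == "linear") fit_linear(x, y)
         else expdecay_fit(x, y)
  params <- if (kind == "linear")
    list(slope = fit$slope, intercept = fit$intercept)
  else as.list(coef(fit))
  list(outcome = outcome, kind = kind, params = params,
       diagnostics = fit$diagnostics, fit = fit)
}

config_echo <- function(config) {
  input <- if (inherits(config$input, "cohort_config")) {
    cc <- unclass(config$input)
    cc$channels <- lapply(cc$channels, unclass)
    list(kind = "generator", config = cc)
  } else list(kind = "file", path = config$input)
  list(input = input,
       analyses = as.list(config$analyses),
       ma_targets = as.list(config$ma_targets),
       n_boot = config$n_boot, seed = config$seed,
       max_crt_r = config$max_crt_r)
}

#' Serialise an analysis report to a plain list / JSON
#'
#' @param x a \code{"teg_analysis"} object.
#' @param path optional path; when given, the report is written as pretty
#'   JSON (UTF-8) and the path returned invisibly.
#' @return the report as a nested list (invisibly, when \code{path} is given).
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "teg_analysis"))
  rep <- list(
    exclusions = unclass(x$exclusions),
    cohort_summary = x$summary,
    fits = lapply(x$fits, function(f)
      list(outcome = f$outcome, kind = f$kind, params = f$params,
           diagnostics = f$diagnostics)),
    cutoffs = lapply(x$cutoffs, function(ct) {
      e <- ct$estimate
      list(y_target = e$y_target, point = e$point,
           boot_median = e$boot_median, boot_q25 = e$boot_q25,
           boot_q75 = e$boot_q75, boot_ci_lo = e$boot_ci_lo,
           boot_ci_hi = e$boot_ci_hi,
           n_boot_requested = e$n_boot_requested,
           n_boot_succeeded = e$n_boot_succeeded,
           performance = unclass(ct$performance))
    }),
    provenance = x$provenance)
  if (is.null(path)) return(rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

write_analysis_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report_json(res, file.path(config$out_dir, "report.json"))
  # numeric curve tables stand in for the scatter/curve figures
  for (f in res$fits) {
    if (f$kind == "linear") {
      g <- seq(min(f$fit$data$x), max(f$fit$data$x), length.out = 100)
      tab <- data.frame(teg_act_s = g, fitted_crt_r_min = predict(f$fit, g))
    } else {
      g <- seq(min(f$fit$data$x), max(f$fit$data$x), length.out = 100)
      tab <- data.frame(crt_r_min = g)
      tab[[paste0("fitted_", f$outcome)]] <- predict(f$fit, g)
    }
    utils::write.csv(tab, file.path(config$out_dir,
                                    paste0("curve_", f$outcome, ".csv")),
                     row.names = FALSE)
  }
  if (length(res$cutoffs)) {
    rows <- lapply(names(res$cutoffs), function(outcome) {
      e <- res$cutoffs[[outcome]]$estimate
      p <- res$cutoffs[[outcome]]$performance
      data.frame(outcome = outcome, y_target = e$y_target, point = e$point,
                 boot_median = e$boot_median, boot_q25 = e$boot_q25,
                 boot_q75 = e$boot_q75, boot_ci_lo = e$boot_ci_lo,
                 boot_ci_hi = e$boot_ci_hi,
                 n_boot_succeeded = e$n_boot_succeeded,
                 sensitivity = p$sensitivity, specificity = p$specificity,
                 ppv = p$ppv, npv = p$npv, accuracy = p$accuracy)
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(config$out_dir, "cutoffs.csv"),
                     row.names = FALSE)
  }
  invisible(config$out_dir)
}

#' @export
print.teg_analysis <- function(x, ...) {
  cat("TEG6s early-prediction analysis\n")
  print(x$exclusions)
  cat("\nChannel relationships (predictor: CRT-R unless linear conversion):\n")
  for (f in x$fits) {
    d <- f$diagnostics
    cat(sprintf("  %-10s %-9s |r| = %.4f  R2 = %.4f  MAE = %.3f  RMSE = %.3f  (n = %d)\n",
                f$outcome, f$kind, d$abs_r, d$r2, d$mae, d$rmse, d$n))
  }
  if (length(x$cutoffs)) {
    cat("\nDerived CRT-R cutoffs:\n")
    for (outcome in names(x$cutoffs)) {
      e <- x$cutoffs[[outcome]]$estimate
      p <- x$cutoffs[[outcome]]$performance
      cat(sprintf("  %s < %g mm: cutoff %.4f min (95%% CI %.4f-%.4f); sens %.1f%%, spec %.1f%%\n",
                  outcome, e$y_target, e$boot_median, e$boot_ci_lo,
                  e$boot_ci_hi, 100 * p$sensitivity, 100 * p$specificity))
    }
  }
  invisible(x)
}
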