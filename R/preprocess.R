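#' Apply the cohort exclusion rules
#'
#' Two-stage filter matching the study design: first drop records with a
#' missing value in any required field, then drop records with CRT-R strictly
#' greater than \code{max_crt_r} (the operative realisation of "more than 5
#' times the upper limit of normal"). The order matters for attribution: a
#' record that is both incomplete and out of range counts as a missingness
#' exclusion.
#'
#' @param data a cohort data.frame (see [simulate_cohort()], [read_teg_csv()]).
#' @param max_crt_r exclusion threshold on CRT-R (min); records with CRT-R
#'   exactly equal are retained.
#' @param fields required fields for the completeness check. Defaults to all
#'   six measurement columns (listwise, the accounting used for the cohort
#'   flow); pass e.g. \code{c("crt_r_min", "cff_ma_mm")} for the pairwise
#'   completeness of a single analysis.
#' @return list with \code{data} (the retained records) and \code{report}, an
#'   \code{"exclusion_report"}: \code{n_initial}, \code{n_missing_excluded},
#'   \code{n_outlier_excluded}, \code{n_final}, \code{max_crt_r}.
#' @export
apply_exclusions <- function(data, max_crt_r = 5.5,
                             fields = teg_measurement_columns()) {
  stopifnot(max_crt_r > 0)
  missing_cols <- setdiff(fields, names(data))
  if (length(missing_cols))
    stop("dataset lacks required column(s): ", paste(missing_cols, collapse = ", "))
  n0 <- nrow(data)
  incomplete <- if (n0) rowSums(is.na(data[, fields, drop = FALSE])) > 0
                else logical(0)
  d1 <- data[!incomplete, , drop = FALSE]
  out_of_range <- if ("crt_r_min" %in% fields) d1$crt_r_min > max_crt_r
                  else rep(FALSE, nrow(d1))
  d2 <- d1[!out_of_range, , drop = FALSE]
  report <- structure(list(n_initial = n0,
                           n_missing_excluded = sum(incomplete),
                           n_outlier_excluded = sum(out_of_range),
                           n_final = nrow(d2),
                           max_crt_r = max_crt_r),
                      class = "exclusion_report")
  list(data = d2, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf(
    "Exclusions: %d initial; %d missing, %d with CRT-R > %.3g min; %d retained\n",
    x$n_initial, x$n_missing_excluded, x$n_outlier_excluded, x$max_crt_r,
    x$n_final))
  invisible(x)
}

#' Per-channel summary statistics of a cohort
#'
#' Median, quartiles and range of the non-missing values of each measurement
#' column. Quartiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7), the convention shared with the bootstrap
#' percentile summaries. An all-missing channel yields an \code{NA} row
#' rather than an error.
#'
#' @param data a cohort data.frame.
#' @param fields columns to summarise; defaults to all six measurements.
#' @return data.frame with one row per channel: \code{channel}, \code{n},
#'   \code{median}, \code{q1}, \code{q3}, \code{min}, \code{max}.
#' @export
summarize_cohort <- function(data, fields = teg_measurement_columns()) {
  rows <- lapply(fields, function(col) {
    v <- data[[col]]
    if (is.null(v)) stop("dataset lacks column '", col, "'")
    v <- v[is.finite(v)]
    if (!length(v))
      return(data.frame(channel = col, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, min = NA_real_,
                        max = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(channel = col, n = length(v), median = q[2L],
               q1 = q[1L], q3 = q[3L], min = min(v), max = max(v))
  })
  do.call(rbind, rows)
}
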