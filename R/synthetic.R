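#' Mean-structure model of one synthetic TEG6s channel
#'
#' Describes how a channel is generated from CRT-R: either an
#' exponential-decay mean curve \code{a*exp(-b*crt_r) + c} plus additive
#' Gaussian noise, clipped to physical bounds, or (for TEG-ACT) the exact
#' inverse of the linear CRT-R/TEG-ACT map \code{crt_r = slope*act +
#' intercept}, so that converting back reproduces CRT-R to float round-off.
#'
#' @param name channel label, one of \code{"CRT-MA"}, \code{"CKH-MA"},
#'   \code{"CFF-MA"}, \code{"CKH-R"}, \code{"TEG-ACT"}.
#' @param kind \code{"exp_decay"} or \code{"linear"}.
#' @param a,b,c decay parameters (channel units; \code{b > 0}, per min);
#'   used when \code{kind = "exp_decay"}.
#' @param slope,intercept the forward map from channel value to CRT-R
#'   (min per s and min); used when \code{kind = "linear"}.
#' @param noise_sd additive Gaussian noise standard deviation (channel units).
#' @param clip_lo,clip_hi physical bounds applied after noise.
#' @return a validated list of class \code{"channel_model"}.
#' @export
channel_model <- function(name, kind = c("exp_decay", "linear"),
                          a = NA_real_, b = NA_real_, c = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          noise_sd = 0, clip_lo = -Inf, clip_hi = Inf) {
  kind <- match.arg(kind)
  valid <- c("CRT-MA", "CKH-MA", "CFF-MA", "CKH-R", "TEG-ACT")
  if (!name %in% valid)
    stop("unknown channel '", name, "'; expected one of ",
         paste(valid, collapse = ", "))
  if (kind == "exp_decay" && (!is.finite(b) || b <= 0))
    stop("exp_decay channel requires decay rate b > 0")
  if (kind == "linear" && (!is.finite(slope) || slope == 0))
    stop("linear channel requires a nonzero slope")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!(clip_lo < clip_hi)) stop("clip_lo must be < clip_hi")
  structure(list(name = name, kind = kind, a = a, b = b, c = c,
                 slope = slope, intercept = intercept, noise_sd = noise_sd,
                 clip_lo = clip_lo, clip_hi = clip_hi,
                 column = .channel_columns[[name]]),
            class = "channel_model")
}

.channel_columns <- c("CRT-MA" = "crt_ma_mm", "CKH-MA" = "ckh_ma_mm",
                      "CFF-MA" = "cff_ma_mm", "CKH-R" = "ckh_r_min",
                      "TEG-ACT" = "teg_act_s")

#' Default channel models of the synthetic cohort
#'
#' One [channel_model()] per TEG6s channel, parameterised by the fitted
#' relationships of the cardiac-surgery cohort: decay curves for the three MA
#' channels and CKH-R (which increases with CRT-R, hence \code{a < 0}), and
#' the deterministic linear TEG-ACT map. Noise standard deviations default to
#' each relationship's residual RMSE; clip bounds are the observed CRT-MA
#' range and physically plausible device ranges for the channels whose range
#' is not otherwise anchored.
#'
#' @return named list of \code{"channel_model"} objects.
#' @export
default_channels <- function() {
  list(
    "CRT-MA" = channel_model("CRT-MA", "exp_decay",
                             a = 39.4557, b = 0.5034, c = 27.5760,
                             noise_sd = 6.5485, clip_lo = 20.1, clip_hi = 75.4),
    "CKH-MA" = channel_model("CKH-MA", "exp_decay",
                             a = 42.0377, b = 0.5107, c = 25.0521,
                             noise_sd = 7.4195, clip_lo = 10, clip_hi = 80),
    "CFF-MA" = channel_model("CFF-MA", "exp_decay",
                             a = 29.9054, b = 0.7345, c = 0.3548,
                             noise_sd = 5.0788, clip_lo = 0, clip_hi = 40),
    "CKH-R" = channel_model("CKH-R", "exp_decay",
                            a = -8.4209, b = 0.8974, c = 11.7798,
                            noise_sd = 3.9846, clip_lo = 0.5, clip_hi = 30),
    "TEG-ACT" = channel_model("TEG-ACT", "linear",
                              slope = 0.0107, intercept = -0.5397,
                              noise_sd = 0))
}

#' Generative configuration of a synthetic paired-measurement cohort
#'
#' The CRT-R marginal is a log-normal truncated to \code{[crt_r_lo,
#' crt_r_hi]}. The default location and spread are calibrated by closed-form
#' quantile inversion so the untruncated distribution has median 0.7 min and
#' quartiles 0.5/0.9 min: \code{crt_r_log_mu = log(0.7)} and
#' \code{crt_r_log_sigma = log(0.9/0.5)/(2 * 0.6745)} (0.6745 is the standard
#' normal upper quartile). Missingness is injected completely at random (one
#' uniformly chosen field per affected record), and a small fraction of
#' records receive out-of-range CRT-R values (> 5.5 min) that the exclusion
#' filter is expected to remove.
#'
#' @param n_records cohort size before exclusions.
#' @param crt_r_log_mu,crt_r_log_sigma log-scale location and spread of the
#'   CRT-R marginal.
#' @param crt_r_lo,crt_r_hi truncation bounds (min).
#' @param missing_rate per-record probability of one missing field.
#' @param outlier_rate per-record probability of an out-of-range CRT-R.
#' @param outlier_lo,outlier_hi range of injected CRT-R outliers (min);
#'   \code{outlier_lo} must exceed 5.5 so every injected record is caught by
#'   the standard exclusion filter.
#' @param seed integer PRNG seed; one stream drives the whole generation.
#' @param channels list of [channel_model()] objects.
#' @return a validated list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_records = 2453,
                          crt_r_log_mu = log(0.7),
                          crt_r_log_sigma = log(0.9 / 0.5) / (2 * 0.6745),
                          crt_r_lo = 0.3, crt_r_hi = 5.5,
                          missing_rate = 80 / 2453,
                          outlier_rate = 24 / 2453,
                          outlier_lo = 5.6, outlier_hi = 20,
                          seed = 1L,
                          channels = default_channels()) {
  if (n_records < 1) stop("n_records must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (outlier_rate < 0 || outlier_rate >= 1) stop("outlier_rate must be in [0, 1)")
  if (crt_r_lo <= 0) stop("crt_r_lo must be > 0")
  if (crt_r_hi <= crt_r_lo) stop("crt_r_hi must exceed crt_r_lo")
  if (crt_r_log_sigma < 0) stop("crt_r_log_sigma must be >= 0")
  if (outlier_rate > 0 && outlier_lo <= 5.5)
    stop("outlier_lo must be > 5.5 min so injected outliers are excludable")
  if (outlier_hi <= outlier_lo) stop("outlier_hi must exceed outlier_lo")
  if (!all(vapply(channels, inherits, logical(1), "channel_model")))
    stop("channels must be a list of channel_model objects")
  structure(list(n_records = as.integer(n_records),
                 crt_r_log_mu = crt_r_log_mu,
                 crt_r_log_sigma = crt_r_log_sigma,
                 crt_r_lo = crt_r_lo, crt_r_hi = crt_r_hi,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 outlier_lo = outlier_lo, outlier_hi = outlier_hi,
                 seed = as.integer(seed), channels = channels),
            class = "cohort_config")
}

#' Draw CRT-R values from the truncated log-normal marginal
#'
#' Inverse-CDF sampling: uniforms on \code{[F(lo), F(hi)]} of the untruncated
#' log-normal are mapped through its quantile function, so the draw is exact
#' (no rejection) and consumes one uniform per record. With zero spread all
#' values equal \code{exp(crt_r_log_mu)}.
#'
#' @param config a [cohort_config()]. Uses the current RNG stream; seed the
#'   stream (or use [simulate_cohort()]) for reproducibility.
#' @param n number of draws, defaulting to \code{config$n_records}.
#' @return numeric vector of CRT-R values (min).
#' @export
sample_crt_r <- function(config, n = config$n_records) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$crt_r_log_sigma == 0)
    return(rep(exp(config$crt_r_log_mu), n))
  p_lo <- stats::plnorm(config$crt_r_lo, config$crt_r_log_mu, config$crt_r_log_sigma)
  p_hi <- stats::plnorm(config$crt_r_hi, config$crt_r_log_mu, config$crt_r_log_sigma)
  u <- stats::runif(n, p_lo, p_hi)
  stats::qlnorm(u, config$crt_r_log_mu, config$crt_r_log_sigma)
}

# channel values given crt_r, drawing noise from the current stream;
# zero-noise channels consume no random numbers
channel_values <- function(ch, crt_r) {
  n <- length(crt_r)
  if (ch$kind == "exp_decay") {
    v <- ch$a * exp(-ch$b * crt_r) + ch$c
    if (ch$noise_sd > 0) v <- v + stats::rnorm(n, 0, ch$noise_sd)
    pmin(pmax(v, ch$clip_lo), ch$clip_hi)
  } else {
    # invert the forward map crt_r = slope*value + intercept exactly
    v <- (crt_r - ch$intercept) / ch$slope
    if (ch$noise_sd > 0) v <- v + stats::rnorm(n, 0, ch$noise_sd)
    v
  }
}

#' Simulate a synthetic paired-measurement cohort
#'
#' Generates a full synthetic TEG6s dataset from a [cohort_config()]: CRT-R
#' values from the truncated log-normal marginal, each channel from its mean
#' structure plus noise (see [channel_model()]), then missingness and CRT-R
#' outliers. A single PRNG stream seeded with \code{config$seed} drives all
#' draws, in this order: CRT-R, channel noise (channels in config order),
#' missingness, outliers — so identical configs give bit-identical datasets.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns \code{record_id}, \code{crt_r_min},
#'   \code{crt_ma_mm}, \code{ckh_r_min}, \code{ckh_ma_mm}, \code{cff_ma_mm},
#'   \code{teg_act_s}; generation metadata in \code{attr(, "provenance")}.
#' @examples
#' d <- simulate_cohort(cohort_config(n_records = 100, seed = 7))
#' summarize_cohort(d)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  local_seed(config$seed)
  n <- config$n_records
  crt_r <- sample_crt_r(config, n)
  d <- data.frame(record_id = seq_len(n), crt_r_min = crt_r)
  for (ch in config$channels) d[[ch$column]] <- channel_values(ch, crt_r)
  for (col in teg_measurement_columns())  # schema columns absent from config
    if (is.null(d[[col]])) d[[col]] <- NA_real_
  d <- d[, c("record_id", teg_measurement_columns())]
  d <- inject_missingness(d, config$missing_rate)
  d <- inject_outliers(d, config$outlier_rate,
                       lo = config$outlier_lo, hi = config$outlier_hi,
                       channels = config$channels)
  prov <- list(config = config, seed = config$seed,
               n_missing_injected = attr(d, "n_missing_injected"),
               n_outliers_injected = attr(d, "n_outliers_injected"))
  attr(d, "n_missing_injected") <- NULL
  attr(d, "n_outliers_injected") <- NULL
  attr(d, "provenance") <- prov
  d
}

#' Inject missing values completely at random
#'
#' Each record is independently affected with probability \code{rate}; an
#' affected record has one uniformly chosen measurement field set to
#' \code{NA}. The affected count is recorded in attribute
#' \code{"n_missing_injected"}.
#'
#' @param data a cohort data.frame (see [simulate_cohort()]).
#' @param rate per-record missingness probability in \code{[0, 1)}.
#' @param seed optional integer seed; \code{NULL} uses the current stream.
#' @return the data.frame with injected \code{NA}s.
#' @export
inject_missingness <- function(data, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (!is.null(seed)) local_seed(seed)
  cols <- teg_measurement_columns()
  n <- nrow(data)
  hit <- which(stats::runif(n) < rate)
  if (length(hit)) {
    field <- sample(cols, length(hit), replace = TRUE)
    for (k in seq_along(hit)) data[hit[k], field[k]] <- NA_real_
  }
  attr(data, "n_missing_injected") <- length(hit)
  data
}

#' Inject out-of-range CRT-R outliers
#'
#' Each record is independently affected with probability \code{rate}; an
#' affected record has its CRT-R replaced by a uniform draw in
#' \code{(lo, hi]} and its channel values regenerated from the same mean
#' structures at the new CRT-R (so the record stays internally consistent).
#' Since \code{lo > 5.5} is required, every injected record is removed by the
#' standard exclusion filter. The injected count is recorded in attribute
#' \code{"n_outliers_injected"}.
#'
#' @param data a cohort data.frame.
#' @param rate per-record outlier probability in \code{[0, 1)}.
#' @param lo,hi outlier CRT-R range (min), \code{lo > 5.5}, \code{hi > lo}.
#' @param seed optional integer seed; \code{NULL} uses the current stream.
#' @param channels channel models used to regenerate affected records.
#' @return the data.frame with injected outliers.
#' @export
inject_outliers <- function(data, rate, lo = 5.6, hi = 20, seed = NULL,
                            channels = default_channels()) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate > 0 && lo <= 5.5)
    stop("lo must be > 5.5 min: injected outliers must not survive the exclusion filter")
  if (rate > 0 && hi <= lo) stop("hi must exceed lo")
  if (!is.null(seed)) local_seed(seed)
  n <- nrow(data)
  hit <- which(stats::runif(n) < rate)
  if (length(hit)) {
    # uniform on (lo, hi]: complement of runif's [0, 1) support
    new_r <- hi - stats::runif(length(hit)) * (hi - lo)
    data$crt_r_min[hit] <- new_r
    for (ch in channels) data[[ch$column]][hit] <- channel_values(ch, new_r)
  }
  attr(data, "n_outliers_injected") <- length(hit)
  data
}

#' Measurement columns of the cohort schema
#'
#' @return character vector of the six measurement column names.
#' @export
teg_measurement_columns <- function() {
  c("crt_r_min", "crt_ma_mm", "ckh_r_min", "ckh_ma_mm", "cff_ma_mm",
    "teg_act_s")
}

#' Write / read a cohort as CSV
#'
#' The on-disk schema is a UTF-8, LF-terminated CSV with header exactly
#' \code{record_id, crt_r_min, crt_ma_mm, ckh_r_min, ckh_ma_mm, cff_ma_mm,
#' teg_act_s}; missing values are empty fields. The round trip is lossless
#' for values and missingness.
#'
#' @param data a cohort data.frame.
#' @param path file path.
#' @return \code{write_teg_csv}: the path, invisibly. \code{read_teg_csv}:
#'   the cohort data.frame. A malformed file (missing column, non-numeric
#'   cell) raises an error naming the offending column (and row).
#' @export
write_teg_csv <- function(data, path) {
  cols <- c("record_id", teg_measurement_columns())
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("dataset lacks required column(s): ", paste(missing_cols, collapse = ", "))
  con <- file(path, open = "wb")  # binary keeps LF endings on any platform
  on.exit(close(con))
  utils::write.csv(data[, cols], con, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_teg_csv
#' @export
read_teg_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                       fileEncoding = "UTF-8")
  cols <- c("record_id", teg_measurement_columns())
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols))
    stop("malformed file '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(record_id = d$record_id)
  for (col in teg_measurement_columns()) {
    raw <- d[[col]]
    raw[raw == ""] <- NA_character_
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(v))
    if (length(bad))
      stop("malformed file '", path, "': non-numeric value in column '", col,
           "', row ", bad[1L])
    out[[col]] <- v
  }
  # ids are integers when they look like integers
  id <- suppressWarnings(as.integer(out$record_id))
  if (!anyNA(id)) out$record_id <- id
  out
}
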