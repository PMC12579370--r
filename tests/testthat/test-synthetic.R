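test_that("identical config gives a bit-identical cohort", {
  cfg <- cohort_config(n_records = 500, seed = 42)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(d1, d2)
})

test_that("degenerate spread collapses CRT-R to a point mass", {
  cfg <- cohort_config(n_records = 20, crt_r_log_sigma = 0, seed = 1,
                       missing_rate = 0, outlier_rate = 0)
  expect_equal(sample_crt_r(cfg), rep(0.7, 20))
})

test_that("CRT-R marginal matches its closed-form truncated quantiles", {
  cfg <- cohort_config(n_records = 50000, seed = 99,
                       missing_rate = 0, outlier_rate = 0)
  # calibration: median exactly 0.7, quartile ratio exactly 0.9/0.5
  expect_equal(cfg$crt_r_log_mu, -0.3567, tolerance = 1e-3)
  expect_equal(cfg$crt_r_log_sigma, 0.4357, tolerance = 1e-3)
  expect_equal(qlnorm(0.5, cfg$crt_r_log_mu, cfg$crt_r_log_sigma), 0.7)
  q_untrunc <- qlnorm(c(0.25, 0.75), cfg$crt_r_log_mu, cfg$crt_r_log_sigma)
  # 1.8 up to the rounding of the conventional probit constant 0.6745
  expect_equal(q_untrunc[2] / q_untrunc[1], 0.9 / 0.5, tolerance = 1e-4)
  # closed form: quartiles land at 0.522 / 0.939 (no log-normal can hit
  # median 0.7 and quartiles 0.5/0.9 simultaneously, 0.7 != sqrt(0.45))
  expect_equal(q_untrunc, c(0.5217515, 0.9391444), tolerance = 1e-6)
  # empirical quantiles converge to the truncated-distribution oracle
  set.seed(99)
  v <- sample_crt_r(cfg)
  truth <- trunc_lnorm_quantile(c(0.25, 0.5, 0.75), cfg$crt_r_log_mu,
                                cfg$crt_r_log_sigma, cfg$crt_r_lo, cfg$crt_r_hi)
  expect_equal(truth, c(0.5355631, 0.7099771, 0.9475812), tolerance = 1e-6)
  expect_equal(unname(quantile(v, c(0.25, 0.5, 0.75))), truth,
               tolerance = 0.015)
  expect_true(all(v >= cfg$crt_r_lo & v <= cfg$crt_r_hi))
})

test_that("noiseless channels lie exactly on their generating curves", {
  d <- simulate_cohort(noiseless_config(n = 150, seed = 3))
  x <- d$crt_r_min
  for (col in names(printed_decay_params)) {
    p <- printed_decay_params[[col]]
    expect_equal(d[[col]], p[["a"]] * exp(-p[["b"]] * x) + p[["c"]],
                 tolerance = 1e-12, label = col)
  }
})

test_that("TEG-ACT channel is the exact inverse of the linear conversion", {
  d <- simulate_cohort(cohort_config(n_records = 300, seed = 8,
                                     missing_rate = 0, outlier_rate = 0))
  expect_equal(d$teg_act_s, (d$crt_r_min + 0.5397) / 0.0107, tolerance = 1e-12)
  # forward map recovers CRT-R to float round-off
  expect_equal(suppressWarnings(act_to_crt_r(d$teg_act_s)), d$crt_r_min,
               tolerance = 1e-12)
})

test_that("calibrated CFF channel reproduces the expected correlation strength", {
  # population |r| = sd(curve)/sqrt(sd(curve)^2 + noise^2) adjusted for
  # clipping, computed by quadrature over the truncated log-normal: 0.5828
  # (the empirical cohort value 0.6224 assumes a slightly more dispersed
  # predictor than the calibrated marginal reproduces)
  cfg <- cohort_config(n_records = 2349, seed = 21,
                       missing_rate = 0, outlier_rate = 0)
  d <- simulate_cohort(cfg)
  ct <- pearson_correlation(d$crt_r_min, d$cff_ma_mm)
  expect_lt(abs(ct$abs_r - 0.5828), 0.045)  # ~3 standard errors at this n
  expect_lt(ct$p_value, 1e-4)
})

test_that("missingness injection is seed-deterministic and rate-faithful", {
  d0 <- simulate_cohort(noiseless_config(n = 10, seed = 5))
  expect_equal(inject_missingness(d0, 0, seed = 1), d0, ignore_attr = TRUE)

  m1 <- inject_missingness(d0, 0.5, seed = 7)
  m2 <- inject_missingness(d0, 0.5, seed = 7)
  expect_identical(m1, m2)
  expect_gt(attr(m1, "n_missing_injected"), 0)
  # one field per affected record
  expect_equal(sum(is.na(m1[teg_measurement_columns()])),
               attr(m1, "n_missing_injected"))

  # n = 2453, rate = 80/2453: affected count within the binomial 95% band
  big <- simulate_cohort(noiseless_config(n = 2453, seed = 13))
  mb <- inject_missingness(big, 80 / 2453, seed = 13)
  band <- qbinom(c(0.025, 0.975), 2453, 80 / 2453)
  k <- attr(mb, "n_missing_injected")
  expect_gte(k, band[1]); expect_lte(k, band[2])

  expect_error(inject_missingness(d0, 1.0), "rate")
})

test_that("outlier injection stays above the exclusion threshold", {
  d0 <- simulate_cohort(noiseless_config(n = 2453, seed = 17))
  expect_equal(inject_outliers(d0, 0, seed = 2), d0, ignore_attr = TRUE)

  o <- inject_outliers(d0, 24 / 2453, lo = 5.6, hi = 20, seed = 17)
  k <- attr(o, "n_outliers_injected")
  band <- qbinom(c(0.025, 0.975), 2453, 24 / 2453)
  expect_gte(k, band[1]); expect_lte(k, band[2])
  injected <- o$crt_r_min > 5.5
  expect_equal(sum(injected), k)
  expect_true(all(o$crt_r_min[injected] > 5.6 - 1e-12))
  # every injected record is removed by the standard filter
  kept <- apply_exclusions(o)$data
  expect_true(all(kept$crt_r_min <= 5.5))

  expect_error(inject_outliers(d0, 0.01, lo = 5.0), "5.5")
})

test_that("CSV round trip is lossless for values and missingness", {
  d <- simulate_cohort(cohort_config(n_records = 80, seed = 31))
  path <- withr::local_tempfile(fileext = ".csv")
  write_teg_csv(d, path)
  back <- read_teg_csv(path)
  expect_equal(back, d[], ignore_attr = TRUE)
  expect_identical(is.na(back), is.na(d[]))

  # empty cohort: header-only file, empty read-back
  empty <- d[0, ]
  write_teg_csv(empty, path)
  back0 <- read_teg_csv(path)
  expect_equal(nrow(back0), 0L)
  expect_named(back0, c("record_id", teg_measurement_columns()))
})

test_that("malformed CSV errors name the offending column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,crt_r_min,crt_ma_mm,ckh_r_min,ckh_ma_mm,cff_ma_mm",
               "1,0.7,54,6,53,18"), path)
  expect_error(read_teg_csv(path), "teg_act_s")

  writeLines(c("record_id,crt_r_min,crt_ma_mm,ckh_r_min,ckh_ma_mm,cff_ma_mm,teg_act_s",
               "1,0.7,54,6,53,18,116",
               "2,oops,54,6,53,18,116"), path)
  expect_error(read_teg_csv(path), "crt_r_min.*row 2")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(cohort_config(n_records = 0), "n_records")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(crt_r_lo = 0), "crt_r_lo")
  expect_error(cohort_config(outlier_lo = 5.0), "5.5")
  expect_error(channel_model("CFF-MA", "exp_decay", a = 1, b = -1, c = 0), "b > 0")
  expect_error(channel_model("CFF-MA", "exp_decay", a = 1, b = 1, c = 0,
                             clip_lo = 2, clip_hi = 1), "clip")
})
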