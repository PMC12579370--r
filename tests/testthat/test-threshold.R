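test_that("closed-form inversion solves the decay equation", {
  cff <- as.list(printed_decay_params$cff_ma_mm)
  # frozen from -(1/b) * log((12 - c)/a) evaluated independently
  expect_equal(invert_exp_decay(cff, 12), 1.2840636, tolerance = 1e-6)

  # value at the origin: y = a + c maps to x = 0
  expect_equal(invert_exp_decay(cff, cff$a + cff$c), 0)

  # roundtrip through the forward curve
  x <- seq(0.3, 5.5, length.out = 40)
  fit <- expdecay(y ~ x, data.frame(
    x = x, y = cff$a * exp(-cff$b * x) + cff$c))
  for (y in c(5, 12, 20, 28))
    expect_equal(predict(fit, invert_exp_decay(fit, y)), y, tolerance = 1e-9)
})

test_that("targets beyond the asymptote raise a distinct no-solution signal", {
  cff <- as.list(printed_decay_params$cff_ma_mm)
  expect_error(invert_exp_decay(cff, 0.2), class = "tegcut_no_solution")
  expect_error(invert_exp_decay(cff, cff$c), class = "tegcut_no_solution")
  err <- tryCatch(invert_exp_decay(cff, -1), condition = function(e) e)
  expect_false(inherits(err, "tegcut_fit_failure"))
})

test_that("inversion is strictly decreasing in the target for decaying curves", {
  cff <- as.list(printed_decay_params$cff_ma_mm)
  ys <- seq(2, 28, length.out = 25)
  xs <- invert_exp_decay(cff, ys)
  expect_true(all(diff(xs) < 0))
})

test_that("bootstrap collapses to the point estimate on noiseless data", {
  set.seed(7)
  x <- runif(120, 0.3, 5.5)
  p <- printed_decay_params$cff_ma_mm
  y <- p[["a"]] * exp(-p[["b"]] * x) + p[["c"]]
  est <- bootstrap_cutoff(x, y, 12, n_boot = 50, seed = 7)
  expect_equal(est$boot_ci_hi - est$boot_ci_lo, 0, tolerance = 1e-6)
  expect_equal(est$boot_median, est$point, tolerance = 1e-6)
  expect_equal(est$n_boot_succeeded, 50L)
})

test_that("bootstrap is seed-deterministic and keeps percentiles ordered", {
  set.seed(11)
  x <- runif(150, 0.3, 5.5)
  p <- printed_decay_params$cff_ma_mm
  y <- p[["a"]] * exp(-p[["b"]] * x) + p[["c"]] + rnorm(150, 0, 5)
  e1 <- bootstrap_cutoff(x, y, 12, n_boot = 100, seed = 123)
  e2 <- bootstrap_cutoff(x, y, 12, n_boot = 100, seed = 123)
  expect_identical(e1[names(e1) != "fit"], e2[names(e2) != "fit"])
  expect_true(e1$boot_ci_lo <= e1$boot_q25 &&
                e1$boot_q25 <= e1$boot_median &&
                e1$boot_median <= e1$boot_q75 &&
                e1$boot_q75 <= e1$boot_ci_hi)
  expect_lte(e1$n_boot_succeeded, e1$n_boot_requested)
  # the percentile summary follows the shared interpolation convention
  expect_equal(e1$boot_median,
               unname(quantile(e1$cutoffs, 0.5, type = 7)))
  expect_equal(e1$boot_ci_lo,
               unname(quantile(e1$cutoffs, 0.025, type = 7)))
})

test_that("an unreachable target makes the bootstrap fail loudly", {
  set.seed(13)
  x <- runif(100, 0.3, 5.5)
  p <- printed_decay_params$cff_ma_mm
  y <- p[["a"]] * exp(-p[["b"]] * x) + p[["c"]] + rnorm(100, 0, 2)
  # a target far below the asymptote can never be reached by the curve
  expect_error(bootstrap_cutoff(x, y, -5, n_boot = 20, seed = 1),
               class = "tegcut_no_solution")
})

test_that("confusion metrics match the constructed 2x2 table", {
  # tp = 2, fp = 1, tn = 6, fn = 1
  crt_r <- c(2, 2, 2, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  ma <- c(10, 10, 20, 10, 20, 20, 20, 20, 20, 20)
  m <- classify_at_cutoff(crt_r, 1, ma, 12)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(2, 1, 6, 1))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$npv, 6 / 7)
  expect_equal(m$accuracy, 0.8)
  expect_length(m$undefined, 0)
})

test_that("perfect separation and tie-breaking behave as specified", {
  crt_r <- c(2, 3, 0.4, 0.6)
  ma <- c(5, 8, 20, 30)
  m <- classify_at_cutoff(crt_r, 1, ma, 12)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)

  # a value exactly at the cutoff is predicted negative
  m2 <- classify_at_cutoff(c(1, 1), 1, c(5, 20), 12)
  expect_equal(m2$tp, 0)
  expect_equal(m2$fn, 1)
})

test_that("zero-denominator metrics are flagged, others still reported", {
  # no actual positives: sensitivity undefined, specificity fine
  m <- classify_at_cutoff(c(0.5, 2), 1, c(20, 25), 12)
  expect_true(is.na(m$sensitivity))
  expect_true("sensitivity" %in% m$undefined)
  expect_equal(m$specificity, 0.5)
})

test_that("raising the cutoff trades sensitivity for specificity", {
  set.seed(303)
  d <- apply_exclusions(simulate_cohort(cohort_config(n_records = 600,
                                                      seed = 303)))$data
  cuts <- seq(0.5, 2.5, by = 0.25)
  ms <- lapply(cuts, function(ct)
    classify_at_cutoff(d$crt_r_min, ct, d$cff_ma_mm, 12))
  sens <- vapply(ms, `[[`, 0, "sensitivity")
  spec <- vapply(ms, `[[`, 0, "specificity")
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("ACT conversions reproduce the published worked examples exactly", {
  expect_equal(round(act_to_crt_r(128), 2), 0.83)
  expect_equal(round(act_to_crt_r(105), 2), 0.58)
  # seconds form: minutes * 60
  expect_equal(round(act_to_crt_r(128) * 60, 1), 49.8)
  expect_equal(act_to_crt_r(105) * 60, 35.028, tolerance = 1e-10)
})

test_that("ACT conversion roundtrips and warns outside the plausible range", {
  for (a in c(60, 105, 128, 199))
    expect_equal(crt_r_to_act(act_to_crt_r(a)), a, tolerance = 1e-12)
  expect_warning(act_to_crt_r(50), "60-199")
  expect_warning(act_to_crt_r(250), "60-199")
  expect_silent(act_to_crt_r(116))
})
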