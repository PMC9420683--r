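test_that("te_curve validates its inputs", {
  expect_error(te_curve(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(te_curve(c(0, 1), c(1, 2, 3)), "equal length")
  expect_error(te_curve(c(0, NA), c(1, 2)), "finite")
  df <- as.data.frame(te_curve(c(0, 1.5), c(40, 41)))
  expect_named(df, c("time_s", "hu"))
})

test_that("baseline estimation finds the pre-arrival level", {
  arrival <- te_curve(0:6 * 1.5, c(40, 40, 40, 90, 150, 200, 210))
  expect_identical(estimate_baseline(arrival), 40)

  flat <- te_curve(0:9, rep(55, 10))
  expect_identical(estimate_baseline(flat), 55)

  # noiseless synthetic organ with contrast arrival after frame 6
  p <- gv_params(100, 35, 9)
  tt <- (0:39) * 1.5
  curve <- te_curve(tt, 35 + gv_enhancement(p, pmax(tt - 7.5, 0)))
  expect_equal(estimate_baseline(curve), 35, tolerance = 1e-9)

  expect_identical(estimate_baseline(arrival, n_pre = 2), 40)
  expect_error(estimate_baseline(te_curve(0, 40)), "at least 2")
})

test_that("gamma-variate fitting recovers noiseless generating parameters", {
  for (a in c(4, 9, 14)) {
    p <- gv_params(120, 33, a)
    fit <- fit_gamma_variate(sampled_curve(p, baseline = 40), baseline = 40)
    expect_true(fit$converged)
    expect_equal(fit$params$y_max, 120, tolerance = 1e-4)
    expect_equal(fit$params$t_max, 33, tolerance = 1e-4)
    expect_equal(fit$params$alpha, a, tolerance = 1e-4)
    expect_lt(fit$rmse, 1e-4)
  }
})

test_that("gamma-variate fitting tolerates additive noise", {
  p <- gv_params(100, 35, 9)
  curve <- sampled_curve(p, baseline = 40)
  noisy <- withr::with_seed(42,
    te_curve(curve$times, curve$values + rnorm(length(curve$times), 0, 5)))
  fit <- fit_gamma_variate(noisy)
  expect_true(fit$converged)
  expect_equal(fit$params$y_max, 100, tolerance = 0.1)
})

test_that("degenerate curves are rejected by the gamma fit", {
  flat <- te_curve(0:9 * 1.5, rep(40, 10))
  expect_error(fit_gamma_variate(flat), "no enhancement")
  expect_error(fit_gamma_variate(te_curve(0:2, c(40, 50, 60))), "4 frames")
})

test_that("fitting is invariant to adding a constant to all samples", {
  p <- gv_params(90, 30, 7)
  curve <- sampled_curve(p, baseline = 40)
  shifted <- te_curve(curve$times, curve$values + 123.4)
  f1 <- fit_gamma_variate(curve)
  f2 <- fit_gamma_variate(shifted)
  expect_equal(f2$params$y_max, f1$params$y_max, tolerance = 1e-6)
  expect_equal(f2$params$t_max, f1$params$t_max, tolerance = 1e-6)
  expect_equal(f2$params$alpha, f1$params$alpha, tolerance = 1e-6)
  expect_equal(f2$baseline_hu - f1$baseline_hu, 123.4, tolerance = 1e-6)
})

test_that("spline maximum slope matches the analytic slope on dense data", {
  p <- gv_params(100, 35, 9)
  dense <- te_curve(seq(0, 60, by = 0.25),
                    gv_enhancement(p, seq(0, 60, by = 0.25)))
  sl <- fit_spline_max_slope(dense, baseline = 0)
  analytic <- gv_max_slope(p, "exact")
  expect_equal(sl$max_slope, analytic, tolerance = 0.02)
  # smoothing attenuates: never above the analytic value by more than 2%
  expect_lt(sl$max_slope, analytic * 1.02)
  expect_equal(sl$at_time, 35 * 2 / 3, tolerance = 0.5)
})

test_that("spline slope handles ramps and degenerate curves", {
  ramp <- te_curve(0:19 * 1.5, 3 * (0:19 * 1.5))
  expect_equal(fit_spline_max_slope(ramp, baseline = 0)$max_slope, 3,
               tolerance = 1e-6)

  flat <- te_curve(0:19 * 1.5, rep(50, 20))
  expect_warning(sl <- fit_spline_max_slope(flat, baseline = 50), "no rising")
  expect_identical(sl$max_slope, 0)

  falling <- te_curve(0:19 * 1.5, 100 - 2 * (0:19 * 1.5))
  expect_warning(sl <- fit_spline_max_slope(falling, baseline = 100), "no rising")
  expect_identical(sl$max_slope, 0)
})

test_that("aortic input fitting recovers peak and bolus shape", {
  ao <- gv_params(350, 14, 9)
  fit <- fit_aortic_input(sampled_curve(ao, baseline = 44))
  expect_s3_class(fit, "aortic_input")
  expect_equal(fit$peak_enhancement, 350, tolerance = 1e-4)
  expect_equal(fit$alpha, 9, tolerance = 1e-4)
  expect_equal(fit$t_max, 14, tolerance = 1e-4)

  noisy <- withr::with_seed(7, {
    base <- sampled_curve(ao, baseline = 44)
    te_curve(base$times, base$values + rnorm(length(base$times), 0, 10))
  })
  nfit <- fit_aortic_input(noisy)
  expect_equal(nfit$alpha, 9, tolerance = 0.15)
  expect_equal(nfit$peak_enhancement, 350, tolerance = 0.1)
})

test_that("a tissue-like slow aortic curve is flagged", {
  slow <- sampled_curve(gv_params(80, 30, 2))
  expect_warning(fit <- fit_aortic_input(slow), "below the clinical")
  expect_lt(fit$alpha, 3)
})

test_that("aortic_input can be built directly from peak and alpha", {
  ao <- aortic_input(350, 9)
  expect_identical(ao$peak_enhancement, 350)
  expect_error(aortic_input(0, 9), "> 0")
  expect_error(aortic_input(350, 1), "> 1")
})
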