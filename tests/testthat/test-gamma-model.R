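p935 <- gv_params(y_max = 100, t_max = 35, alpha = 9)

test_that("gamma-variate curve evaluates to the closed-form values", {
  expect_identical(gv_enhancement(p935, 35), 100)
  expect_identical(gv_enhancement(p935, 0), 0)
  # 100 * 0.5^9 * exp(4.5), frozen from high-precision evaluation
  expect_equal(gv_enhancement(p935, 17.5), 17.5814709571, tolerance = 1e-10)

  # unimodal: increases up to t_max, decreases after
  tt <- seq(0.5, 120, by = 0.5)
  y <- gv_enhancement(p935, tt)
  expect_true(all(diff(y[tt <= 35]) > 0))
  expect_true(all(diff(y[tt >= 35]) < 0))
})

test_that("invalid times and parameters are rejected", {
  expect_error(gv_enhancement(p935, -1), "negative")
  expect_error(gv_enhancement(p935, c(1, NaN)), "finite")
  expect_error(gv_slope(p935, -0.5), "negative")
  expect_error(gv_params(100, 35, 1), "alpha")
  expect_error(gv_params(100, 0, 9), "t_max")
  expect_error(gv_params(-1, 35, 9), "y_max")
})

test_that("curve slope matches finite differences and has the right signs", {
  expect_equal(gv_slope(p935, 35), 0)
  tt <- c(5, 12, 20, 28, 34, 40, 60, 80)
  expect_equal(gv_slope(p935, tt), fd_slope(p935, tt), tolerance = 1e-6)
  expect_true(all(gv_slope(p935, c(5, 20, 30)) > 0))
  expect_true(all(gv_slope(p935, c(40, 60)) < 0))
  # slope vanishes nowhere else on (0, t_max)
  interior <- seq(0.1, 34.9, by = 0.1)
  expect_true(all(gv_slope(p935, interior) > 0))
})

test_that("slope is maximal at the ascending inflection time", {
  t_infl <- 35 * gv_inflection_times(9)[["ascending"]] # 35 * 6/9
  expect_equal(gv_slope(p935, t_infl), gv_max_slope(p935, "exact"),
               tolerance = 1e-12)
  expect_equal(gv_slope(p935, t_infl), numeric_max_slope(p935),
               tolerance = 1e-6)
})

test_that("inflection roots are (alpha +/- sqrt(alpha)) / alpha", {
  expect_equal(unname(gv_inflection_times(4)), c(0.5, 1.5))
  expect_equal(unname(gv_inflection_times(9)), c(2 / 3, 4 / 3))
  expect_equal(unname(gv_inflection_times(3)), c(0.42265, 1.57735),
               tolerance = 1e-5)
  expect_true(gv_inflection_times(1.2)[["ascending"]] > 0)
  expect_true(gv_inflection_times(50)[["ascending"]] < 1)
  expect_error(gv_inflection_times(1), "> 1")
  expect_error(gv_inflection_times(0.5), "> 1")
})

test_that("exact k matches frozen high-precision values and grows with alpha", {
  expect_equal(k_exact(4), 1.84726402473, tolerance = 1e-10)
  expect_equal(k_exact(9), 2.35111909115, tolerance = 1e-10)
  expect_equal(k_exact(3), 1.74880718484, tolerance = 1e-10)
  a <- seq(3, 15, by = 0.25)
  expect_true(all(k_exact(a) > 0))
  expect_true(all(diff(k_exact(a)) > 0))
  expect_error(k_exact(1), "> 1")
})

test_that("exact k reproduces brute-force slope maximisation across alpha", {
  for (a in c(3, 5, 9, 12, 15)) {
    p <- gv_params(80, 30, a)
    expect_equal(80 * k_exact(a) / 30, numeric_max_slope(p),
                 tolerance = 1e-4)
  }
})

test_that("linearised k is exact arithmetic and warns outside [3, 15]", {
  expect_identical(k_linear(9), 1.502 + 0.092016 * 9)
  expect_equal(k_linear(9), 2.330144)
  expect_equal(k_linear(15), 2.88224)
  expect_warning(out <- k_linear(0), "\\[3, 15\\]")
  expect_identical(out, 1.502)
  expect_silent(k_linear(c(3, 15)))
})

test_that("linearised k stays within 2% of exact k on the clinical range", {
  a <- seq(3, 15, by = 0.01)
  expect_lt(max(abs(k_linear(a) - k_exact(a)) / k_exact(a)), 0.02)
})

test_that("analytic maximum slope is y_max * k / t_max", {
  expect_equal(gv_max_slope(p935, "exact"), 6.71748311756, tolerance = 1e-10)
  expect_equal(gv_max_slope(p935, "linear"), 6.65755428571, tolerance = 1e-10)
  expect_identical(gv_max_slope(gv_params(0, 35, 9), "exact"), 0)
})

test_that("perfusion from curve parameters divides max slope by aortic peak", {
  est <- perfusion_from_params(p935, 350)
  expect_s3_class(est, "perfusion_estimate")
  expect_identical(est$method, "gamma_two_phase")
  expect_equal(est$perfusion, 0.0190215836735, tolerance = 1e-10)
  expect_equal(perfusion_per_min(est), 1.14129502041, tolerance = 1e-10)
  expect_equal(est$perfusion, est$max_slope / est$aortic_peak)

  expect_identical(perfusion_from_params(gv_params(0, 35, 9), 350)$perfusion, 0)
  # linear in y_max
  est2 <- perfusion_from_params(gv_params(200, 35, 9), 350)
  expect_equal(est2$perfusion, 2 * est$perfusion)
  expect_error(perfusion_from_params(p935, 0), "> 0")
  expect_error(perfusion_from_params(p935, -5), "> 0")
})

test_that("enhancement prediction inverts the perfusion equation", {
  # worked organ predictions: ~100 HU pancreas, ~220 HU renal cortex
  expect_equal(enhancement_from_perfusion(1.15 / 60, 350, 35, 9),
               100.762728255, tolerance = 1e-9)
  expect_equal(enhancement_from_perfusion(2.5 / 60, 350, 35, 9),
               219.04940925, tolerance = 1e-9)
  expect_identical(enhancement_from_perfusion(0, 350, 35, 9), 0)
  expect_error(enhancement_from_perfusion(0.02, 0, 35, 9), "> 0")

  # round trip to machine precision for both k modes
  for (mode in c("linear", "exact")) {
    for (a in c(3, 6, 9, 15)) {
      for (y in c(10, 100, 220)) {
        p <- gv_params(y, 35, a)
        perf <- perfusion_from_params(p, 350, k_mode = mode)$perfusion
        expect_equal(enhancement_from_perfusion(perf, 350, 35, a, k_mode = mode),
                     y, tolerance = 1e-10)
      }
    }
  }
})

test_that("aortic peak prediction follows the dilution model", {
  expect_equal(predict_aortic_peak(injection_protocol(3.2, 350, 83)),
               353.272289157, tolerance = 1e-9)
  # the modelled protocol rounds to the nominal 350 dHU
  expect_equal(predict_aortic_peak(injection_protocol(3.2, 350, 83)), 350,
               tolerance = 0.01)
  expect_identical(predict_aortic_peak(injection_protocol(0, 350, 83)), 0)
  expect_equal(predict_aortic_peak(injection_protocol(5, 350, 83.33)),
               549.80199208, tolerance = 1e-9)
  expect_error(injection_protocol(3.2, 350, 0), "cardiac_output")
})

test_that("perfusion ratio equals enhancement ratio for shared kinetics", {
  expect_identical(perfusion_ratio_from_enhancement(100, 100), 1)
  expect_identical(perfusion_ratio_from_enhancement(220, 100), 2.2)
  expect_error(perfusion_ratio_from_enhancement(100, 0), "> 0")

  # both sides computed independently for two organs sharing the aortic input
  p1 <- perfusion_from_params(gv_params(220, 35, 9), 350)$perfusion
  p2 <- perfusion_from_params(gv_params(100, 35, 9), 350)$perfusion
  expect_equal(p1 / p2, perfusion_ratio_from_enhancement(220, 100),
               tolerance = 1e-12)
})
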