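test_that("parametric driver evaluates the normalised Gaussian pulse", {
  d <- cvs_driver(0.75, peak_frac = 0.4, width = 80)
  # direct evaluation of exp(-W (t - t_peak)^2)
  expect_equal(driver_value(d, 0.2), exp(-80 * 0.01), tolerance = 1e-12)
  # maximum of exactly 1 at the peak, periodically repeated
  expect_equal(driver_value(d, 0.3), 1)
  expect_equal(driver_value(d, 0.3 + 0.75), 1)
  expect_equal(driver_value(d, 0.3 - 3 * 0.75), 1)
})

test_that("driver is periodic and bounded in [0, 1]", {
  d <- cvs_driver(0.6)
  t <- seq(0, 0.6, length.out = 241)
  v <- driver_value(d, t)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(v, driver_value(d, t + 5 * 0.6), tolerance = 1e-9)
  # a single global maximum per period
  expect_equal(sum(abs(v[-length(v)] - 1) < 1e-12), 1L)
})

test_that("default pulse width scales with the period", {
  # same normalised shape at every heart rate: value at a fixed phase
  # fraction is rate independent
  for (T in c(0.375, 0.5, 0.75)) {
    d <- cvs_driver(T)
    expect_equal(driver_value(d, 0.1 * T), exp(-45 * (0.1 - 0.3)^2),
                 tolerance = 1e-12)
  }
  # the reference period of 0.75 s reproduces W = 80 1/s^2
  expect_equal(cvs_driver(0.75)$width, 80)
})

test_that("sampled drivers normalise, clip and interpolate periodically", {
  y <- pmax(sin(seq(0, pi, length.out = 50)), 0) * 3
  d <- sampled_driver(y, 0.5)
  expect_equal(max(driver_value(d, seq(0, 0.5, by = 0.002))), 1,
               tolerance = 1e-3)
  expect_gte(min(driver_value(d, seq(0, 0.5, by = 0.002))), 0)
  expect_equal(driver_value(d, 0.12), driver_value(d, 0.62),
               tolerance = 1e-12)
})

test_that("invalid drivers are rejected", {
  expect_error(cvs_driver(0), "period")
  expect_error(cvs_driver(-1), "period")
  expect_error(sampled_driver(rep(0, 10), 0.5), "identically zero")
  expect_error(driver_value(cvs_driver(0.5), Inf), "finite")
})
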