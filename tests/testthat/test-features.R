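test_that("beat means and amplitudes follow their definitions", {
  expect_equal(waveform_mean(rep(80, 50)), 80)
  tri <- c(seq(60, 100, length.out = 26), seq(100, 60, length.out = 26)[-1])
  expect_equal(waveform_mean(tri[-length(tri)]), 80, tolerance = 1e-6)
  expect_equal(waveform_amplitude(tri), 40)
  expect_equal(waveform_amplitude(rep(7, 10)), 0)
  expect_error(waveform_mean(numeric(0)), "2 samples")
  expect_error(waveform_amplitude(numeric(0)), "empty")
})

test_that("maximum ascending gradient recovers known slopes", {
  # constant ramp 0 -> 100 mmHg over 0.5 s
  expect_equal(max_ascending_gradient(seq(0, 100, length.out = 101),
                                      f_s = 200), 200, tolerance = 1e-6)
  expect_equal(max_ascending_gradient(rep(5, 50), f_s = 200), 0)
  # sine of amplitude A at angular frequency w has max slope A * w
  f_s <- 1000
  t <- seq(0, 1, by = 1 / f_s)
  A <- 20; w <- 2 * pi * 3
  expect_equal(max_ascending_gradient(A * sin(w * t), f_s), A * w,
               tolerance = 0.02 * A * w)
  expect_error(max_ascending_gradient(1:3, 200), "shorter")
})

test_that("stroke volume averages the two ventricular amplitudes", {
  v1 <- c(seq(30, 100, length.out = 40), seq(100, 30, length.out = 40))
  v2 <- 0.5 * (v1 - mean(v1)) + mean(v1)  # half the amplitude
  expect_equal(stroke_volume(v1, v1), waveform_amplitude(v1))
  expect_equal(stroke_volume(rep(0, 10) + 70, rep(0, 10) + 10), 0)
  # an underestimated right ventricular amplitude drags the average:
  # (A + A/2) / 2 = 0.75 A
  expect_equal(stroke_volume(v1, v2), 0.75 * waveform_amplitude(v1))
})

test_that("global end diastolic volume is the sum of the two sides", {
  expect_equal(gedv(97.7, 93.3), 191.0)
  expect_equal(gedv(0, 0), 0)
  expect_equal(gedv(3, 8), gedv(8, 3))
  expect_error(gedv(-1, 5), ">= 0")
})

test_that("end diastolic volume is the filling maximum", {
  v <- c(seq(60, 110, length.out = 50), seq(110, 60, length.out = 50))
  expect_equal(end_diastolic_volume(v), 110)
  expect_equal(end_diastolic_volume(rep(42, 20)), 42)
  # simulated beat: the volume maximum coincides with mitral closure
  w <- one_steady_beat("closed")
  t_mt <- cvsid:::closure_time_from_flow(w$Q_mt, w$t, w$P_pu - w$P_lv)
  v_at_close <- approx(w$t, w$V_lv, xout = t_mt)$y
  expect_lt(abs(end_diastolic_volume(w$V_lv) - v_at_close), 1)
})

test_that("driver estimation is normalised and locates the peak", {
  w <- one_steady_beat("closed")
  d <- estimate_driver(w$P_ao, period = 0.5, f_s = 200)
  g <- driver_value(d, seq(0, 0.5, by = 0.0025))
  expect_equal(max(g), 1, tolerance = 1e-6)
  expect_gte(min(g), 0)
  # the generating driver peaked at 30% of the period; recovery within
  # a tenth of the period
  expect_lt(abs(driver_peak_time(d) - 0.3 * 0.5), 0.1 * 0.5)
  # degenerate input falls back to the parametric driver, flagged
  d0 <- estimate_driver(rep(90, 100), period = 0.5, f_s = 200)
  expect_true(isTRUE(attr(d0, "fallback")))
})

test_that("valve closure time matches the parametric closed form", {
  d <- cvs_driver(0.75, peak_frac = 0.4, width = 80)
  delta <- 0.05
  expect_equal(valve_closure_time(d, delta),
               0.3 - sqrt(log(1 / delta) / 80), tolerance = 1e-9)
  # threshold approaching 1 pushes the read-off towards the peak
  expect_lt(abs(valve_closure_time(d, 0.999) - 0.3), 0.01)
  # a shifted sampled driver shifts the closure time equally
  y <- driver_value(d, seq(0, 0.75, length.out = 301)[-301])
  s <- sampled_driver(y, 0.75)
  shift <- 60L  # samples = 0.15 s
  s2 <- sampled_driver(c(tail(y, shift), head(y, -shift)), 0.75)
  expect_equal(valve_closure_time(s2, delta),
               (valve_closure_time(s, delta) + 0.15) %% 0.75,
               tolerance = 0.01)
  expect_error(valve_closure_time(d, 1.2), "between 0 and 1")
})

test_that("set points extracted from a simulation match its internals", {
  p <- cvs_params()
  w <- steady_state_beat(p)
  sp <- extract_setpoints(w, smooth_window = 0)
  expect_equal(sp$MAP, waveform_mean(w$P_ao), tolerance = 1e-3)
  expect_equal(sp$SV, stroke_volume(w$V_lv, w$V_rv), tolerance = 1e-3)
  expect_equal(sp$GEDV, max(w$V_lv) + max(w$V_rv), tolerance = 1e-3)
  expect_equal(sp$T, 0.5)
  expect_silent(validate_setpoints(sp))
  # invariance to which steady-state beat is selected
  w8 <- simulate_cvs(p, n_beats = 8, init = attr(w, "final_state"))
  sp8 <- extract_setpoints(w8, smooth_window = 0)
  for (col in c("MAP", "MPAP", "PP_ao", "PP_pa", "SV", "GEDV"))
    expect_lt(abs(sp8[[col]] - sp[[col]]) / sp[[col]], 1e-3)
})

test_that("extraction is stable across sampling rates", {
  p <- cvs_params()
  ref <- extract_setpoints(steady_state_beat(p, f_s = 1000))
  for (fs in c(100, 200, 400)) {
    spf <- extract_setpoints(steady_state_beat(p, f_s = fs))
    expect_lt(abs(spf$MAP - ref$MAP) / ref$MAP, 0.005)
    expect_lt(abs(spf$PP_ao - ref$PP_ao) / ref$PP_ao, 0.005)
    expect_lt(abs(spf$SV - ref$SV) / ref$SV, 0.005)
  }
})

test_that("inconsistent set points are rejected", {
  sp <- extract_setpoints(one_steady_beat("closed"))
  bad <- sp
  bad$SV <- bad$GEDV + 1
  expect_error(validate_setpoints(bad), "GEDV")
  bad2 <- sp
  bad2$t_mt <- sp$T + 0.1
  expect_error(validate_setpoints(bad2), "t_mt")
})
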