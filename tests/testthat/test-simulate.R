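test_that("closed-loop simulation conserves total blood volume", {
  p <- cvs_params()
  w <- simulate_cvs(p, n_beats = 20)
  tot <- w$V_lv + w$V_ao + w$V_vc + w$V_rv + w$V_pa + w$V_pu
  expect_lt(max(abs(tot - p$V_total)), 1e-3)
})

test_that("valve flows never reverse", {
  w <- simulate_cvs(cvs_params(), n_beats = 5)
  for (q in c("Q_mt", "Q_av", "Q_tc", "Q_pv"))
    expect_gte(min(w[[q]]), 0)
})

test_that("solution is insensitive to halving the solver tolerances", {
  p <- cvs_params()
  w1 <- steady_state_beat(p, rtol = 1e-7, atol = 1e-7)
  w2 <- steady_state_beat(p, rtol = 5e-8, atol = 5e-8)
  expect_lt(max(abs(w1$P_ao - w2$P_ao)), 0.1)
})

test_that("output length and sampling structure are as requested", {
  p <- cvs_params(heart_rate = 120)   # period 0.5 s
  w <- simulate_cvs(p, n_beats = 1, f_s = 200)
  expect_equal(nrow(w), 100)
  expect_equal(w$t[2] - w$t[1], 1 / 200)
  w3 <- simulate_cvs(p, n_beats = 3, f_s = 100)
  expect_equal(nrow(w3), 150)
  expect_error(simulate_cvs(p, n_beats = 0), "n_beats")
})

test_that("steady state is a fixed point and a global attractor", {
  p <- cvs_params()
  w <- steady_state_beat(p)
  expect_true(attr(w, "converged"))
  # one further beat changes the state by less than the tolerance
  s <- attr(w, "final_state")
  w2 <- simulate_cvs(p, n_beats = 1, init = s)
  last <- unlist(w[nrow(w), c("V_lv", "V_ao", "V_vc", "V_rv", "V_pa",
                              "V_pu")])
  first <- unlist(w2[nrow(w2), c("V_lv", "V_ao", "V_vc", "V_rv", "V_pa",
                                 "V_pu")])
  expect_lt(max(abs(first - last)), 0.05)
  # an idempotent restart reproduces the same beat
  w3 <- steady_state_beat(p, init = s)
  expect_lt(max(abs(w3$P_ao - w$P_ao)), 0.1)
  # two different physiological starting states reach the same cycle
  alt <- s * c(1.15, 0.9, 1.1, 0.85, 1.2, 0.95)
  alt <- alt * (p$V_total / sum(alt))
  w4 <- steady_state_beat(p, init = alt)
  expect_lt(max(abs(w4$P_ao - w$P_ao) / max(w$P_ao)), 0.001)
  expect_lt(max(abs(w4$V_lv - w$V_lv) / max(w$V_lv)), 0.001)
})

test_that("periodic steady state is reached from the standard start", {
  w <- steady_state_beat(cvs_params())
  expect_true(attr(w, "converged"))
  expect_lte(attr(w, "beats_run"), 300)
  ws <- steady_state_beat(cvs_params(), mode = "systemic")
  wp <- steady_state_beat(cvs_params(), mode = "pulmonary")
  expect_true(attr(ws, "converged") && attr(wp, "converged"))
})

test_that("steady-state responses move in physiological directions", {
  base <- cvs_params()
  w0 <- steady_state_beat(base)
  up <- function(field, fac = 1.05) {
    a <- list(fac * base[[field]])
    names(a) <- field
    steady_state_beat(do.call(cvs_params, a))
  }
  # higher systemic resistance raises mean aortic pressure
  expect_gt(mean(up("R_sys")$P_ao), mean(w0$P_ao))
  # stiffer aorta raises the aortic pulse pressure
  expect_gt(diff(range(up("E_ao")$P_ao)), diff(range(w0$P_ao)))
  # stronger left ventricle empties further: smaller LVEDV
  expect_lt(max(up("E_es_lvf")$V_lv), max(w0$V_lv))
  # a tighter mitral valve reduces stroke volume
  expect_lt(stroke_volume(up("R_mt", 1.05)$V_lv, up("R_mt", 1.05)$V_rv),
            stroke_volume(w0$V_lv, w0$V_rv))
})
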