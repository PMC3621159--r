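test_that("ventricular free-wall pressure blends ESPVR and EDPVR", {
  # fully activated: linear end-systolic relation
  expect_equal(ventricle_pressure(73, dri = 1, E_es = 2, V_d = 23), 100)
  # relaxed with zero EDPVR scale: no passive pressure at any volume
  expect_equal(ventricle_pressure(150, dri = 0, E_es = 2, V_d = 23,
                                  P_0 = 0, lambda = 0.033), 0)
  # relaxed exponential EDPVR, direct evaluation
  expect_equal(ventricle_pressure(100, dri = 0, E_es = 2, V_d = 23,
                                  P_0 = 1, lambda = 0.033, V_0 = 0),
               exp(3.3) - 1, tolerance = 1e-12)
})

test_that("passive chambers are linearly elastic", {
  expect_equal(passive_pressure(40, E = 2.5), 100)
  expect_equal(passive_pressure(17, E = 3, V_d = 17), 0)
  expect_equal(passive_pressure(10, E = 2.1), 21)
})

test_that("pericardial pressure follows its exponential law", {
  p <- cvs_params()
  # V_lv + V_rv at the pericardial volume offset: zero pressure
  pr <- compute_pressures(list(V_lv = 100, V_ao = 40, V_vc = 40,
                               V_rv = 100, V_pa = 10, V_pu = 40),
                          t = 0.35, params = p)
  expect_equal(pr$P_pcd, 0, tolerance = 1e-12)
  # printed constants at V_lv + V_rv = 250
  pr2 <- compute_pressures(list(V_lv = 125, V_ao = 40, V_vc = 40,
                                V_rv = 125, V_pa = 10, V_pu = 40),
                           t = 0.35, params = p)
  expect_equal(pr2$P_pcd, 0.5003 * (exp(1.5) - 1), tolerance = 1e-12)
})

test_that("septum solver matches a dense bisection oracle", {
  set.seed(42)
  p <- cvs_params()
  for (i in 1:20) {
    V_lv <- runif(1, 40, 160)
    V_rv <- runif(1, 40, 160)
    dL <- runif(1, 0.001, 1)
    dR <- runif(1, 0.001, 1)
    pp <- cvs_params(E_es_lvf = runif(1, 0.5, 4),
                     E_es_rvf = runif(1, 0.3, 2))
    expect_equal(septum_volume(V_lv, V_rv, dL, dR, pp),
                 septum_bisect(V_lv, V_rv, dL, dR, pp),
                 tolerance = 1e-6)
  }
})

test_that("septal volume solves known symmetric configurations and is
           monotone in left ventricular volume", {
  p <- cvs_params(E_es_rvf = 2)  # match left and right free walls
  p$V_d_rvf <- p$V_d_lvf
  p$lambda_rvf <- p$lambda_lvf
  # fully relaxed symmetric heart: both free walls exert zero pressure
  # (their EDPVR scale is zero), so the septum rests at its own
  # zero-pressure volume V_0_spt
  expect_equal(septum_volume(100, 100, 0, 0, p), p$V_0_spt,
               tolerance = 1e-6)
  # fully activated symmetric heart: the linear balance
  # E_spt (x - V_d_spt) = -2 E x has the closed-form root
  x_ref <- p$E_es_spt * p$V_d_spt / (p$E_es_spt + 2 * p$E_es_lvf)
  expect_equal(septum_volume(100, 100, 1, 1, p), x_ref,
               tolerance = 1e-6)
  # a fuller left ventricle pushes the septum rightward
  vs <- vapply(seq(80, 140, by = 10), function(v)
    septum_volume(v, 100, 0.5, 0.5, cvs_params()), numeric(1))
  expect_true(all(diff(vs) >= 0))
})

test_that("valve flows are pressure-gated diodes, vascular flows Ohmic", {
  p <- cvs_params()
  pr <- list(P_lv = 8, P_ao = 100, P_vc = 5, P_rv = 4, P_pa = 20, P_pu = 5)
  q <- compute_flows(pr, p)
  expect_equal(q$Q_mt, 0)           # upstream below ventricular pressure
  expect_equal(q$Q_av, 0)           # aorta above ventricle
  expect_equal(q$Q_sys, (100 - 5) / p$R_sys)
  pr0 <- lapply(pr, function(x) 50)
  q0 <- compute_flows(pr0, p)
  expect_true(all(unlist(q0) == 0))
  # Ohmic arithmetic with the standard initial resistance
  pr1 <- list(P_lv = 8, P_ao = 100, P_vc = 5, P_rv = 4, P_pa = 20,
              P_pu = 5)
  expect_equal(compute_flows(pr1, cvs_params(R_sys = 2.5))$Q_sys, 38)
})

test_that("chamber derivatives conserve total volume", {
  p <- cvs_params()
  set.seed(7)
  for (i in 1:10) {
    s <- list(V_lv = runif(1, 50, 150), V_ao = runif(1, 20, 60),
              V_vc = runif(1, 10, 80), V_rv = runif(1, 50, 150),
              V_pa = runif(1, 5, 30), V_pu = runif(1, 10, 80))
    d <- cvs_derivatives(s, t = runif(1, 0, 0.5), p)
    expect_equal(sum(unlist(d)), 0, tolerance = 1e-10)
  }
})

test_that("submodel derivatives drop the fixed source chamber", {
  p <- cvs_params()
  d <- cvs_derivatives(list(V_lv = 100, V_ao = 40), t = 0.4, p,
                       mode = "systemic")
  expect_named(d, c("V_lv", "V_ao"))
  d2 <- cvs_derivatives(list(V_rv = 100, V_pa = 10), t = 0.4, p,
                        mode = "pulmonary")
  expect_named(d2, c("V_rv", "V_pa"))
})

test_that("compiled integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- cvs_params()
  w0 <- one_steady_beat("closed")
  init <- unlist(w0[1, c("V_lv", "V_ao", "V_vc", "V_rv", "V_pa", "V_pu")])
  rhs <- function(t, y, parms) {
    list(unlist(cvs_derivatives(setNames(as.list(y), names(init)), t, p)))
  }
  times <- seq(0, p$driL$period, by = 1 / 200)
  ref <- deSolve::lsoda(init, times, rhs, NULL, rtol = 1e-8, atol = 1e-8)
  mine <- simulate_cvs(p, n_beats = 1, f_s = 200, init = init)
  expect_lt(max(abs(mine$V_lv - ref[-nrow(ref), "V_lv"])), 0.05)
  expect_lt(max(abs(mine$V_pa - ref[-nrow(ref), "V_pa"])), 0.05)
})
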