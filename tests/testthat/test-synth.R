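test_that("baseline sampling is reproducible and screened", {
  b1 <- sample_baseline(1)
  b2 <- sample_baseline(1)
  expect_equal(unclass(b1$params), unclass(b2$params))
  b3 <- sample_baseline(2)
  expect_false(identical(unclass(b1$params), unclass(b3$params)))
  for (b in list(b1, b3)) {
    expect_gte(b$screen[["MAP"]], 50)
    expect_lte(b$screen[["MAP"]], 130)
    expect_gte(b$screen[["SV"]], 20)
    expect_lte(b$screen[["SV"]], 60)
    # balanced end diastolic volumes by construction
    expect_lt(abs(b$screen[["lv_share"]] - 0.5), 0.006)
  }
})

test_that("septic trajectories follow the configured trends", {
  b <- sample_baseline(1)
  flat <- septic_trajectory(b, sepsis_config(r_sys_drop = 0,
                                             r_pul_rise = 0, hr_rise = 0))
  for (tp in flat) expect_equal(tp$R_sys, b$params$R_sys)
  traj <- septic_trajectory(b, sepsis_config())
  # full configured drop reached at the 120-minute timepoint
  expect_equal(traj$T120$R_sys, 0.58 * b$params$R_sys, tolerance = 1e-9)
  expect_equal(traj$T120$R_pul, 1.5 * b$params$R_pul, tolerance = 1e-9)
  # monotone fall to the trough, flat thereafter for a non-responder
  rs <- vapply(traj, function(p) p$R_sys, numeric(1))
  expect_true(all(diff(rs[1:5]) <= 1e-12))
  expect_equal(unname(rs["T240"]), unname(rs["T120"]))
  # contractility held constant
  el <- vapply(traj, function(p) p$E_es_lvf, numeric(1))
  expect_equal(unname(el), rep(b$params$E_es_lvf, 9))
  # responders recover towards baseline after the trough
  resp <- septic_trajectory(b, sepsis_config(responder = TRUE))
  rr <- vapply(resp, function(p) p$R_sys, numeric(1))
  expect_gte(unname(rr["T240"]), min(rr))
})

test_that("noiseless generated data round trips through extraction", {
  b <- sample_baseline(3)
  ds <- generate_dataset(b, sepsis_config(n_timepoints = 2, noise_sd = 0),
                         seed = 1)
  expect_length(ds$failed, 0)
  sp <- ds$setpoints$T0
  tr <- ds$truth$T0$outputs
  expect_lt(abs(sp$MAP - tr$MAP) / tr$MAP, 0.005)
  expect_lt(abs(sp$SV - tr$SV) / tr$SV, 0.005)
  expect_lt(abs(sp$GEDV - tr$GEDV) / tr$GEDV, 0.005)
})

test_that("generation is deterministic in the seed", {
  b <- sample_baseline(4)
  cfg <- sepsis_config(n_timepoints = 1)
  d1 <- generate_dataset(b, cfg, seed = 9)
  d2 <- generate_dataset(b, cfg, seed = 9)
  expect_identical(d1$waveforms$T0$P_ao, d2$waveforms$T0$P_ao)
  d3 <- generate_dataset(b, cfg, seed = 10)
  expect_false(identical(d1$waveforms$T0$P_ao, d3$waveforms$T0$P_ao))
  dir <- withr::local_tempdir()
  write_dataset <- getFromNamespace("write_dataset", "cvsid")
  write_dataset(d1, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "waveforms_T0.csv")))
})

test_that("right-ventricular amplitude bias scales measurements only", {
  b <- sample_baseline(5)
  cfg0 <- sepsis_config(n_timepoints = 1, noise_sd = 0, rv_factor = 1)
  cfg5 <- sepsis_config(n_timepoints = 1, noise_sd = 0, rv_factor = 0.5)
  d0 <- generate_dataset(b, cfg0, seed = 1)
  d5 <- generate_dataset(b, cfg5, seed = 1)
  a0 <- diff(range(d0$waveforms$T0$V_rv))
  a5 <- diff(range(d5$waveforms$T0$V_rv))
  expect_equal(a5 / a0, 0.5, tolerance = 1e-6)
  # ground truth untouched
  expect_equal(d5$truth$T0$outputs$RVEDV, d0$truth$T0$outputs$RVEDV)
})
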