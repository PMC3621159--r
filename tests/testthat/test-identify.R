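test_that("proportional-gain updates follow the two update rules", {
  expect_equal(proportional_update(2, measurement = 90, model_output = 60),
               3)
  expect_equal(proportional_update(2, measurement = 60, model_output = 90,
                                   relation = "inverse"), 3)
  # measurement == output is a fixed point
  expect_equal(proportional_update(1.7, 42, 42), 1.7)
  expect_equal(proportional_update(1.7, 42, 42, "inverse"), 1.7)
  expect_error(proportional_update(-1, 2, 2), "invalid update")
  expect_error(proportional_update(1, 0, 2), "invalid update")
})

test_that("update directions are resolved by sensitivity sign", {
  cfg <- identification_config()
  p <- cvs_params()
  # resistance raises mean pressure; stiffer aorta raises pulse pressure
  expect_equal(relation_direction("R_sys", "MAP", p, "systemic", cfg),
               "proportional")
  expect_equal(relation_direction("E_ao", "PP_ao", p, "systemic", cfg),
               "proportional")
  # stronger contraction empties the ventricle
  expect_equal(relation_direction("E_es_lvf", "LVEDV", p, "systemic", cfg),
               "inverse")
  # results are cached per configuration
  expect_identical(ls(cfg$relation_cache),
                   sort(c("R_sys:MAP:systemic", "E_ao:PP_ao:systemic",
                          "E_es_lvf:LVEDV:systemic")))
})

test_that("within-stage updates are order invariant", {
  # all updates in one pass read the same simulated-output snapshot, so
  # permuting the pairing order cannot change the result
  pairs <- list(
    list(param = "R_sys", output = "MAP", target = "MAP"),
    list(param = "E_ao", output = "PP_ao", target = "PP_ao"),
    list(param = "E_es_lvf", output = "LVEDV", target = "half_GEDV"))
  outs <- list(MAP = 80, PP_ao = 30, LVEDV = 90)
  meas <- list(MAP = 95, PP_ao = 36, half_GEDV = 100)
  rel <- c("R_sys:MAP" = "proportional", "E_ao:PP_ao" = "proportional",
           "E_es_lvf:LVEDV" = "inverse")
  p <- cvs_params()
  a <- cvsid:::apply_updates(p, pairs, outs, meas, rel, 1, c(0.5, 2))
  set.seed(1)
  b <- cvsid:::apply_updates(p, sample(pairs), outs, meas, rel, 1,
                             c(0.5, 2))
  for (n in c("R_sys", "E_ao", "E_es_lvf"))
    expect_identical(a[[n]], b[[n]])
})

test_that("afterload elastance follows its definition", {
  expect_equal(afterload_metric(0.03, 0.4, 0.5), 0.86)
  expect_equal(afterload_metric(0.03, 0.4, 1), 0.43)
  expect_equal(afterload_metric(0, 0, 0.5), 0)
})

test_that("contradictory set points are rejected before identification", {
  sp <- extract_setpoints(one_steady_beat("closed"))
  sp$SV <- sp$GEDV + 10
  expect_error(identify_submodel(sp, "systemic"), "GEDV")
  expect_error(identify_model(sp), "GEDV")
})

test_that("submodel identification reproduces a submodel's own outputs", {
  # set points taken from a decoupled systemic simulation with known
  # parameters; identification starting at those parameters must keep
  # all matched outputs at their measured values
  cfg <- identification_config()
  p <- cvs_params(E_es_lvf = 2.3, R_sys = 2.1, E_ao = 2.8, R_mt = 0.06,
                  R_av = 0.045, heart_rate = 100)
  w <- steady_state_beat(p, mode = "systemic")
  outs <- cvsid:::model_outputs(w, "systemic", cfg)
  sp <- tibble::tibble(
    GEDV = 2 * outs$LVEDV, SV = outs$SV_lv, MAP = outs$MAP,
    MPAP = 15, PP_ao = outs$PP_ao, PP_pa = 20,
    dPao_max = outs$dPao_max, dPpa_max = 300,
    t_mt = outs$t_mt, t_tc = 0.05, T = 0.6, heart_rate = 100)
  init <- list(E_es_lvf = 2.3, R_sys = 2.1, E_ao = 2.8, R_mt = 0.06,
               R_av = 0.045, P_pu = 5)
  fit <- identify_submodel(sp, "systemic", init = init, cfg = cfg)
  expect_true(fit$converged)
  expect_lt(max(fit$residuals$residual_pct), 0.5)
  # parameters essentially unchanged from the generating values
  for (n in names(init))
    expect_lt(abs(fit$estimates[[n]] - init[[n]]) / init[[n]], 0.02)
})

test_that("identification initialised at ground truth stays there", {
  b <- sample_baseline(3)
  ds <- generate_dataset(b, sepsis_config(n_timepoints = 1, noise_sd = 0),
                         seed = 3)
  truth <- ds$truth$T0$params
  fit <- identify_model(ds$setpoints$T0, identification_config(),
                        init = truth)
  expect_true(fit$converged)
  for (n in c("E_es_lvf", "E_es_rvf", "R_sys", "R_pul", "E_ao", "E_pa"))
    expect_lt(abs(fit$params[[n]] - truth[[n]]) / truth[[n]], 0.02)
})

test_that("full staged identification matches its measurements", {
  b <- sample_baseline(2)
  ds <- generate_dataset(b, sepsis_config(n_timepoints = 1, noise_sd = 0),
                         seed = 2)
  fit <- identify_model(ds$setpoints$T0)
  five <- subset(fit$residuals,
                 output %in% c("MAP", "MPAP", "PP_ao", "PP_pa", "SV_lv",
                               "SV_rv"))
  expect_lt(max(five$residual_pct), 0.5)
  truth <- ds$truth$T0$params
  # headline parameters recovered
  for (n in c("E_es_lvf", "R_sys", "E_ao"))
    expect_lt(abs(fit$params[[n]] - truth[[n]]) / truth[[n]], 0.05)
  # tidy/glance interfaces
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(unname(td$estimate[td$term == "R_sys"]), fit$params$R_sys)
  gl <- glance(fit)
  expect_equal(gl$RVAC,
               fit$params$E_es_rvf /
                 afterload_metric(fit$params$R_pv, fit$params$R_pul,
                                  fit$params$driL$period))
})

test_that("a single-timepoint series re-identifies to the same model", {
  b <- sample_baseline(5)
  ds <- generate_dataset(b, sepsis_config(n_timepoints = 1, noise_sd = 0),
                         seed = 5)
  ser <- identify_subject(list(ds$setpoints$T0))
  # averaging over one timepoint is the identity
  expect_equal(ser$valve_resistances[["R_mt"]],
               ser$fits$T0$params$R_mt)
  # second pass shares the averaged valves and stays close to pass one
  for (v in c("R_mt", "R_av", "R_tc", "R_pv"))
    expect_equal(ser$refits$T0$params[[v]], ser$valve_resistances[[v]])
  for (n in c("E_es_lvf", "R_sys", "E_ao"))
    expect_lt(abs(ser$refits$T0$params[[n]] - ser$fits$T0$params[[n]]) /
                ser$fits$T0$params[[n]], 0.02)
  td <- tidy(ser)
  expect_true(all(c("timepoint", "term", "estimate") %in% names(td)))
})
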