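# shared fixtures: small parameter sets and simulated beats, built once
default_params <- function(...) cvs_params(...)

one_steady_beat <- local({
  cache <- new.env(parent = emptyenv())
  function(mode = "closed") {
    if (is.null(cache[[mode]]))
      cache[[mode]] <- steady_state_beat(cvs_params(), mode = mode)
    cache[[mode]]
  }
})

# brute-force septum root by dense bisection, independent of the solver
septum_bisect <- function(V_lv, V_rv, driL, driR, p) {
  g <- function(x) {
    P_spt <- driL * p$E_es_spt * (x - p$V_d_spt) +
      (1 - driL) * p$P_0_spt * expm1(p$lambda_spt * (x - p$V_0_spt))
    P_l <- driL * p$E_es_lvf * ((V_lv - x) - p$V_d_lvf) +
      (1 - driL) * p$P_0_lvf * expm1(p$lambda_lvf * ((V_lv - x) - p$V_0_lvf))
    P_r <- driR * p$E_es_rvf * ((V_rv + x) - p$V_d_rvf) +
      (1 - driR) * p$P_0_rvf * expm1(p$lambda_rvf * ((V_rv + x) - p$V_0_rvf))
    P_spt - (P_l - P_r)
  }
  lo <- -500; hi <- 500
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
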