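test_that("clearance assembly reflects pathway dominance by lipophilicity", {
  tmz_spec <- cns_model_spec(drug_tmz(), rat_phys(), load_plasma_model("tmz_sf188"))
  cl <- build_clearances(tmz_spec)
  share <- cl$cl_para / (cl$cl_para + (cl$cl_tc_in + cl$cl_tc_out) / 2)
  expect_gte(share, 0.996)   # hydrophilic: paracellular-dominant
  let_spec <- cns_model_spec(drug_let(), rat_phys(), load_plasma_model("let_c6"))
  cll <- build_clearances(let_spec)
  share_l <- cll$cl_para / (cll$cl_para + (cll$cl_tc_in + cll$cl_tc_out) / 2)
  expect_lt(share_l, 0.2)    # lipophilic: transcellular-dominant
  expect_gt(share_l, 0.05)
})

test_that("the paracellular correction factor divides only cl_para", {
  s1 <- cns_model_spec(drug_tmz(), rat_phys(), load_plasma_model("tmz_sf188"),
                       ppa_correction = 1)
  s2 <- s1; s2$ppa_correction <- 2
  c1 <- build_clearances(s1); c2 <- build_clearances(s2)
  expect_equal(c2$cl_para, c1$cl_para / 2)
  for (f in c("cl_tc_in", "cl_tc_out", "cl_ecf_bulk", "q_cbf", "cl_wo",
              "cl_ow", "cl_lyso", "cl_para_bcsfb"))
    expect_equal(c2[[f]], c1[[f]], label = f)
})

test_that("simulation conserves mass and scales linearly with dose", {
  spec <- mtx_spec()
  tt <- seq(0, 360, by = 30)
  d <- dose_event("iv_bolus", 50000)
  sim <- simulate_cns(spec, d, tt)
  mb <- attr(sim, "mass_balance")
  expect_true(all(abs(mb$rel_error[-1]) < 1e-3))   # closed balance (0.1%)
  expect_true(all(sim$conc_ng_per_ml >= 0))
  # zero dose stays identically zero; doubling the dose doubles everything
  sim0 <- simulate_cns(spec, dose_event("iv_bolus", 1e-300), tt)
  expect_true(all(sim0$conc_ng_per_ml < 1e-250))
  sim2 <- simulate_cns(spec, dose_event("iv_bolus", 100000), tt)
  expect_equal(sim2$conc_ng_per_ml[-(1:13)], 2 * sim$conc_ng_per_ml[-(1:13)],
               tolerance = 1e-6)
})

test_that("lsoda simulation matches an independent matrix-exponential oracle", {
  spec <- probe_base()
  tt <- seq(0, 120, by = 30)
  sim <- simulate_cns(spec, NULL, tt, plasma_fn = function(t) rep(200, length(t)))
  sys <- btbpk:::assemble_system(spec)
  n <- sys$n_obs  # bookkeeping states never feed back; drop them
  A <- sys$A[seq_len(n), seq_len(n)]
  b <- sys$b[seq_len(n)]
  # constant forcing: x(t) = A^-1 (e^{At} - I) b * cp  via Pade expm
  cp <- 200 / 1000
  xs <- sapply(tt[-1], function(t) {
    E <- expm_pade(A * t)
    solve(A, (E - diag(n)) %*% (b * cp))
  })
  conc_oracle <- 1000 * xs / sys$volumes[seq_len(n)]
  for (k in seq_len(sys$n_obs)) {
    got <- sim$conc_ng_per_ml[sim$compartment == sys$state_names[k]][-1]
    expect_equal(got, unname(conc_oracle[k, ]), tolerance = 1e-5,
                 label = sys$state_names[k])
  }
})

test_that("steady-state Kp_uu closed form agrees with the long-time ODE ratio", {
  for (build in list(function() mtx_spec(),
                     function() probe_base(),
                     function() cns_model_spec(drug_tmz(), rat_phys(),
                                               load_plasma_model("tmz_sf188"),
                                               kpuu_ecf_target = 0.262))) {
    spec <- build()
    cl <- build_clearances(spec)
    sim <- simulate_cns(spec, NULL, times = c(0, 20000),
                        plasma_fn = function(t) rep(100, length(t)))
    ecf <- sim$conc_ng_per_ml[sim$compartment == "brain_ecf"][2]
    expect_equal(ecf / 100, steady_state_kpuu(cl), tolerance = 0.01)
  }
})

test_that("Kp_uu algebra: symmetry, limits, scaling invariance", {
  spec <- cns_model_spec(drug_tmz(), rat_phys(), load_plasma_model("tmz_sf188"))
  cl <- build_clearances(spec)
  # symmetric passive barrier with no bulk flow drain gives exactly 1
  cl0 <- cl; cl0$cl_ecf_bulk <- 0
  expect_equal(steady_state_kpuu(cl0), 1)
  # growing active efflux drives Kp_uu monotonically to 0
  kp <- vapply(c(1, 100, 1e4, 1e6), function(af) {
    c2 <- cl; c2$af_out <- af; c2$cl_act_out <- (af - 1) * c2$cl_tc_out
    steady_state_kpuu(c2)
  }, 0)
  expect_true(all(diff(kp) < 0))
  expect_lt(kp[4], 0.01)
  # common scaling of all clearances cancels
  cs <- cl
  for (f in c("cl_para", "cl_tc_in", "cl_tc_out", "cl_act_in", "cl_act_out",
              "cl_ecf_bulk"))
    cs[[f]] <- cs[[f]] * 7.3
  expect_equal(steady_state_kpuu(cs), steady_state_kpuu(cl))
})

test_that("asymmetry factors invert the measured Kp_uu exactly", {
  spec <- cns_model_spec(drug_let(), rat_phys(), load_plasma_model("let_c6"))
  cl <- build_clearances(spec)
  passive <- steady_state_kpuu(cl)
  expect_equal(af_from_kpuu(passive, cl), c(af_in = 1, af_out = 1))
  for (k in 10^seq(-3, 0.5, length.out = 8)) {
    afs <- af_from_kpuu(k, cl)
    c2 <- cl
    c2$af_in <- afs[["af_in"]]; c2$af_out <- afs[["af_out"]]
    c2$cl_act_in <- (c2$af_in - 1) * c2$cl_tc_in
    c2$cl_act_out <- (c2$af_out - 1) * c2$cl_tc_out
    expect_equal(steady_state_kpuu(c2), k, tolerance = 1e-6)
    expect_true(sum(afs > 1) <= 1)   # at most one side is active
  }
  expect_error(af_from_kpuu(-1, cl), "positive")
})

test_that("the healthy barrier shows net efflux for every bundled study", {
  # all measured control Kp_uu,ECF lie below the passive prediction, so the
  # inward asymmetry factor is always 1 (net active efflux)
  st <- load_study_table()
  st <- st[st$species == "rat", ]
  for (i in seq_len(nrow(st))) {
    spec <- cns_model_spec(load_drug(st$drug[i]), rat_phys(),
                           plasma_1cmt(),
                           ppa_correction = max(st$ppa_correction[i], 1, na.rm = TRUE))
    afs <- af_from_kpuu(st$kpuu_control[i], build_clearances(spec))
    expect_equal(afs[["af_in"]], 1, label = st$study[i])
    expect_gte(afs[["af_out"]], 1)
  }
  # letrozole without correction reproduces the published magnitude
  spec <- cns_model_spec(drug_let(), rat_phys(), load_plasma_model("let_c6"))
  afs <- af_from_kpuu(0.786, build_clearances(spec))
  expect_equal(afs[["af_out"]], 1.30, tolerance = 0.005)
})

test_that("acidic tumor ECF lowers the steady-state exposure of acids", {
  # acids are less ionized at lower pH, so the donor-side pH factor of the
  # outward (ECF -> plasma) transcellular route grows and Kp_uu falls
  mk <- function(ph_ecf) {
    phys <- rat_phys(); phys$ph_ecf <- ph_ecf
    spec <- cns_model_spec(drug_mtx(), phys, plasma_1cmt(),
                           ppa_correction = 1000)  # transcellular regime
    steady_state_kpuu(build_clearances(spec))
  }
  expect_lt(mk(6.87), mk(7.30))
})
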