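# Noise-free single-subject dataset generated from known truth.
clean_study <- function(base, tum, folds, doses, ppa = NULL, seed = 5) {
  if (!is.null(ppa)) base$ppa_correction <- ppa
  pm <- base$plasma; pm$sigma_prop <- 0; pm$sigma_add <- 0
  pm$omega_cl <- 0; pm$omega_v <- 0
  d <- study_design(base$drug, base$physiology, tum, pm, doses,
                    n_subjects = 1, kpuu_control = base$kpuu_ecf_target,
                    true_ppa_correction = base$ppa_correction,
                    true_folds = folds, seed = seed)
  generate_study(d)
}

test_that("the paracellular correction is recovered from clean control data", {
  base <- cns_model_spec(drug_mtx(), rat_phys(), load_plasma_model("mtx_rg2"),
                         ppa_correction = 1, kpuu_ecf_target = 0.114)
  tum <- load_tumor_model("RG-2")
  doses <- list(dose_event("iv_bolus", 50000))
  ds <- clean_study(base, tum, fold_changes(1, 1), doses, ppa = 14)
  fit <- estimate_ppa_correction(ds$observations, base, doses,
                                 starts = 10^seq(0, 2, length.out = 3))
  expect_equal(fit$ppa_correction, 14, tolerance = 0.01)
  # null case: data simulated without any correction
  ds1 <- clean_study(base, tum, fold_changes(1, 1), doses, ppa = 1)
  fit1 <- estimate_ppa_correction(ds1$observations, base, doses,
                                  starts = 10^seq(-0.5, 1.5, length.out = 3))
  expect_equal(fit1$ppa_correction, 1, tolerance = 0.05)
  expect_error(estimate_ppa_correction(ds$observations[1:2, ], base, doses),
               "at least 3")
})

test_that("fold changes are recovered simultaneously from clean tumor data", {
  base <- probe_base()
  tum <- load_tumor_model("C6")
  doses <- list(dose_event("iv_bolus", 4000))
  base$ppa_correction <- 14
  ds <- clean_study(base, tum, fold_changes(7.46, 0.131), doses)
  tsp <- tumor_model_spec(base, tum, fold_changes())
  fit <- estimate_fold_changes(ds$observations, tsp, doses, seed = 1,
                               f_pore_grid = 10^seq(-0.5, 2, length.out = 3),
                               f_efflux_grid = c(-1, 0.5, 3))
  expect_equal(fit$f_pore, 7.46, tolerance = 0.05)
  expect_equal(fit$f_efflux, 0.131, tolerance = 0.05)
  expect_false(fit$ridge_flag)
  # null case: near the passive point the pore fold has little leverage for
  # this drug, so its tolerance is wider
  ds1 <- clean_study(base, tum, fold_changes(1, 1), doses)
  fit1 <- estimate_fold_changes(ds1$observations, tsp, doses, seed = 1,
                                f_pore_grid = 10^seq(-0.5, 1.5, length.out = 3),
                                f_efflux_grid = c(-0.5, 0.8, 2))
  expect_equal(fit1$f_pore, 1, tolerance = 0.3)
  expect_equal(fit1$f_efflux, 1, tolerance = 0.1)
})

test_that("paracellular-dominant drugs ride an identifiability ridge", {
  base <- mtx_spec()       # methotrexate, correction 14, Kp_uu 0.114
  tum <- load_tumor_model("RG-2")
  doses <- list(dose_event("iv_bolus", 50000))
  pm <- base$plasma; pm$sigma_prop <- 0.15; pm$sigma_add <- 0
  d <- study_design(base$drug, base$physiology, tum, pm, doses,
                    n_subjects = 6, kpuu_control = base$kpuu_ecf_target,
                    true_ppa_correction = base$ppa_correction,
                    true_folds = fold_changes(2.66, 0.392), seed = 5)
  ds <- generate_study(d)
  tsp <- tumor_model_spec(base, tum, fold_changes())
  fit <- estimate_fold_changes(ds$observations, tsp, doses, seed = 1)
  expect_true(fit$ridge_flag)
  expect_gt(fit$start_dispersion, 0.1)
  # the separate protocol (one parameter fixed to 1) is well determined
  fit_p <- estimate_fold_changes(ds$observations, tsp, doses, seed = 1,
                                 fix = "f_efflux")
  expect_false(fit_p$ridge_flag)
  expect_identical(fit_p$fixed_parameter, "f_efflux")
  expect_equal(fit_p$f_efflux, 1)
  fit_e <- estimate_fold_changes(ds$observations, tsp, doses, seed = 1,
                                 fix = "f_pore")
  expect_false(fit_e$ridge_flag)
  expect_equal(fit_e$f_pore, 1)
})

test_that("the objective is invariant to row order and joint unit rescaling", {
  base <- probe_base()
  base$ppa_correction <- 14
  tum <- load_tumor_model("C6")
  doses <- list(dose_event("iv_bolus", 4000))
  ds <- clean_study(base, tum, fold_changes(3, 0.5), doses)
  tsp <- tumor_model_spec(base, tum, fold_changes())
  grids <- list(f_pore_grid = c(1, 10), f_efflux_grid = c(0.2, 2))
  f1 <- do.call(estimate_fold_changes,
                c(list(ds$observations, tsp, doses, seed = 1), grids))
  shuffled <- ds$observations[rev(seq_len(nrow(ds$observations))), ]
  f2 <- do.call(estimate_fold_changes,
                c(list(shuffled, tsp, doses, seed = 1), grids))
  expect_equal(f1$f_pore, f2$f_pore, tolerance = 1e-8)
  expect_equal(f1$objective_value, f2$objective_value, tolerance = 1e-8)
  # rescale dose and observations together (unit change)
  obs_scaled <- ds$observations
  obs_scaled$conc_ng_per_ml <- obs_scaled$conc_ng_per_ml * 1000
  f3 <- do.call(estimate_fold_changes,
                c(list(obs_scaled, tsp, list(dose_event("iv_bolus", 4e6)),
                       seed = 1), grids))
  expect_equal(f3$f_pore, f1$f_pore, tolerance = 1e-6)
  expect_equal(f3$f_efflux, f1$f_efflux, tolerance = 1e-6)
})

test_that("estimation predictions agree with the reference simulator", {
  base <- probe_base(); base$ppa_correction <- 14
  tum <- load_tumor_model("C6")
  doses <- list(dose_event("iv_bolus", 4000))
  tsp <- tumor_model_spec(base, tum, fold_changes(7.46, 0.131))
  obs <- data.frame(subject_id = "S1", compartment = "tumor_ecf",
                    time_min = seq(0, 340, 20), interval_end_min = seq(20, 360, 20),
                    conc_ng_per_ml = 1, censored = FALSE)
  ref <- predict_observations(tsp, doses, obs, rtol = 1e-10, atol = 1e-12)
  sys <- btbpk:::assemble_tumor_subsystem(tsp)
  og <- btbpk:::obs_grid(obs)
  fast <- og$extract(btbpk:::analytic_forced_conc(base$plasma, doses, sys$A,
                                                  sys$b, 2L, sys$volumes[2],
                                                  og$grid))
  expect_equal(fast, ref, tolerance = 1e-6)
})
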