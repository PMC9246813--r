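test_that("bolus, lag and pre-dose behaviour match the closed forms", {
  m <- plasma_1cmt(cl = 5, v = 200)
  d <- dose_event("iv_bolus", amount = 1000)
  out <- simulate_plasma(m, d, c(0, 1e-9, 60))
  expect_equal(out$conc_ng_per_ml[1], 0)                      # pre-dose
  expect_equal(out$conc_ng_per_ml[2], 1000 * 1000 / 200,      # D/V at t=0+
               tolerance = 1e-6)
  # 1-cmt bolus is a mono-exponential
  t3 <- out$time_min[3]
  expect_equal(out$conc_ng_per_ml[3], 5000 * exp(-5 / 200 * t3),
               tolerance = 1e-9)
  # depot with lag predicts exactly zero before the lag
  g <- load_plasma_model("gcv_bt4c")
  expect_equal(g$lag, 19.3)
  outg <- simulate_plasma(g, dose_event("depot", 1000), c(0, 5, 19, 19.29, 25))
  expect_true(all(outg$conc_ng_per_ml[1:4] == 0))
  expect_gt(outg$conc_ng_per_ml[5], 0)
})

test_that("closed-form solutions match a numerical ODE oracle", {
  times <- seq(0, 360, by = 5)
  for (study in load_plasma_table()$study) {
    m <- load_plasma_model(study)
    has_dep <- !is.null(m$k_a)
    d <- if (has_dep) dose_event("depot", 2000) else dose_event("iv_bolus", 2000)
    pred <- simulate_plasma(m, d, times)$conc_ng_per_ml
    # oracle: numerical integration of the same rate matrix with dosing as
    # an initial condition at the (lagged) dose time
    sys <- btbpk:::plasma_matrix(m)
    t0 <- if (has_dep && !is.null(m$lag)) m$lag else 0
    y0 <- numeric(sys$n)
    y0[if (has_dep) sys$depot else sys$central] <- 2000
    tt <- sort(unique(c(t0, times[times >= t0])))
    num <- ode_oracle(sys$A, numeric(sys$n), function(t) 0, tt - t0, y0 = y0)
    ref <- rep(0, length(times))
    ref[times >= t0] <- 1000 * num[sys$central, match(times[times >= t0], tt)] / m$v_cen
    ref[times <= t0] <- 0  # the dose instant itself is pre-dose
    expect_equal(pred, ref, tolerance = 1e-6, label = study)
  }
})

test_that("infusions superpose and match the ODE oracle", {
  m <- load_plasma_model("mtx_rg2")  # two-compartment
  d <- dose_event("iv_infusion", amount = 6000, start = 10, duration = 30)
  times <- seq(0, 240, by = 2)
  pred <- simulate_plasma(m, d, times)$conc_ng_per_ml
  sys <- btbpk:::plasma_matrix(m)
  rate_fn <- function(t) ifelse(t > 10 & t <= 40, 200, 0)
  b <- numeric(sys$n); b[sys$central] <- 1
  num <- ode_oracle(sys$A, b, rate_fn, times)
  expect_equal(pred, 1000 * num[sys$central, ] / m$v_cen, tolerance = 1e-5)
  # linearity: doubling every dose doubles every concentration
  two <- simulate_plasma(m, list(d, dose_event("iv_bolus", 500, start = 60)),
                         times)$conc_ng_per_ml
  four <- simulate_plasma(m, list(dose_event("iv_infusion", 12000, 10, duration = 30),
                                  dose_event("iv_bolus", 1000, start = 60)),
                          times)$conc_ng_per_ml
  expect_equal(four, 2 * two, tolerance = 1e-10)
})

test_that("exponential IIV deviations act on clearance and volume", {
  m <- plasma_1cmt(cl = 5, v = 200)
  d <- dose_event("iv_bolus", 1000)
  eta <- c(cl = 0.3, v = -0.2)
  ind <- simulate_plasma(m, d, c(30, 120), eta = eta)$conc_ng_per_ml
  m2 <- plasma_1cmt(cl = 5 * exp(0.3), v = 200 * exp(-0.2))
  expect_equal(ind, simulate_plasma(m2, d, c(30, 120))$conc_ng_per_ml)
  # eta = 0 reduces to the population prediction
  expect_equal(simulate_plasma(m, d, c(30, 120), eta = c(cl = 0, v = 0)),
               simulate_plasma(m, d, c(30, 120)))
})

test_that("residual error model reproduces its moments and determinism", {
  pred <- data.frame(conc_ng_per_ml = rep(100, 1e5))
  m0 <- plasma_1cmt(sigma_prop = 0, sigma_add = 0)
  expect_identical(apply_ruv(pred, m0, seed = 1)$conc_ng_per_ml,
                   pred$conc_ng_per_ml)
  m <- plasma_1cmt(sigma_prop = 0.1, sigma_add = 0)
  a <- apply_ruv(pred, m, seed = 7)
  b <- apply_ruv(pred, m, seed = 7)
  expect_identical(a, b)                               # bit-identical replay
  expect_equal(sd(a$conc_ng_per_ml) / 100, 0.1, tolerance = 0.01)
  # combined model floors negatives and flags them
  madd <- plasma_1cmt(sigma_prop = 0, sigma_add = 50)
  small <- apply_ruv(data.frame(conc_ng_per_ml = rep(1, 1000)), madd, seed = 3)
  expect_true(any(small$floored))
  expect_true(all(small$conc_ng_per_ml >= 0))
})

test_that("pooled ML fitting recovers a one-compartment model", {
  true <- plasma_1cmt(cl = 8, v = 250)
  d <- dose_event("iv_bolus", 5000)
  ts <- c(2, 5, 10, 20, 40, 60, 90, 120, 180, 240)
  clean <- simulate_plasma(true, d, ts)
  dat <- data.frame(subject_id = "S1", time_min = ts,
                    conc_ng_per_ml = clean$conc_ng_per_ml)
  fit <- fit_plasma(dat, d, structure = "one_compartment", n_starts = 4)
  expect_equal(fit$cl_cen, 8, tolerance = 1e-3)
  expect_equal(fit$v_cen, 250, tolerance = 1e-3)
  # degenerate and non-identifiable inputs fail loudly
  expect_error(fit_plasma(transform(dat, conc_ng_per_ml = 0), d,
                          "one_compartment"), "zero")
  expect_error(fit_plasma(dat[1:2, ], d, "two_compartment"),
               "non-identifiable")
})

test_that("fitted clearance is nearly unbiased under proportional noise", {
  true <- plasma_1cmt(cl = 8, v = 250, sigma_prop = 0.1)
  d <- dose_event("iv_bolus", 5000)
  ts <- rep(c(2, 5, 10, 20, 40, 60, 90, 120, 180, 240), each = 50)  # 500 obs
  clean <- simulate_plasma(true, d, sort(unique(ts)))
  pred <- clean$conc_ng_per_ml[match(ts, clean$time_min)]
  biases <- vapply(1:20, function(s) {
    noisy <- apply_ruv(data.frame(conc_ng_per_ml = pred), true, seed = 100 + s)
    dat <- data.frame(subject_id = "S1", time_min = ts,
                      conc_ng_per_ml = noisy$conc_ng_per_ml)
    fit <- fit_plasma(dat, d, "one_compartment", n_starts = 2, seed = s)
    (fit$cl_cen - 8) / 8
  }, 0)
  expect_lt(abs(median(biases)), 0.02)
})

test_that("per-subject refits provide IIV standard deviations", {
  true <- plasma_1cmt(cl = 8, v = 250, sigma_prop = 0.05,
                      omega_cl = 0.3, omega_v = 0.2)
  d <- dose_event("iv_bolus", 5000)
  ts <- c(2, 5, 10, 20, 40, 60, 90, 120, 180, 240)
  set.seed(42)
  dat <- do.call(rbind, lapply(1:8, function(s) {
    eta <- c(cl = rnorm(1, 0, 0.3), v = rnorm(1, 0, 0.2))
    pred <- simulate_plasma(true, d, ts, eta = eta)
    noisy <- apply_ruv(pred, true)
    data.frame(subject_id = sprintf("S%d", s), time_min = ts,
               conc_ng_per_ml = noisy$conc_ng_per_ml)
  }))
  fit <- fit_plasma(dat, d, "one_compartment", n_starts = 3, seed = 2)
  expect_gt(fit$omega_cl, 0.1)   # variability detected
  expect_lt(fit$omega_cl, 0.6)   # and of the right magnitude
  expect_equal(fit$cl_cen, 8, tolerance = 0.25)
})

test_that("dose and model constructors enforce their contracts", {
  expect_error(dose_event("iv_bolus", -5), "positive")
  expect_error(dose_event("iv_infusion", 100), "duration")
  expect_error(plasma_pk_model("one_compartment", cl_cen = 5, k_el = 0.1,
                               v_cen = 100), "exactly one")
  expect_error(plasma_pk_model("one_compartment", v_cen = 100), "exactly one")
  expect_error(plasma_pk_model("one_compartment", cl_cen = 5, v_cen = 100,
                               lag = 10), "lag")
  expect_error(plasma_pk_model("two_compartment", cl_cen = 5, v_cen = 100),
               "two-compartment")
  expect_error(simulate_plasma(plasma_1cmt(), dose_event("iv_bolus", 1),
                               c(10, 5)), "sorted")
})
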