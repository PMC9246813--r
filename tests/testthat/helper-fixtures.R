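# Shared fixtures and independent oracles for the test suite.

rat_phys <- function() default_physiology("rat")

drug_mtx <- function() load_drug("methotrexate")
drug_tmz <- function() load_drug("temozolomide")
drug_let <- function() load_drug("letrozole")

# A strongly effluxed, moderately lipophilic neutral compound:
# transcellular-dominant barrier transport with a sizeable active component
# and tumor equilibration slow enough that both barrier rate and extent are
# observable; used where fold-change identifiability is required.
drug_probe <- function() {
  drug_properties("probe", mw = 300, charge_class = "neutral", logp = 1.0,
                  fup = 1)
}

plasma_1cmt <- function(cl = 5, v = 200, ...) {
  plasma_pk_model("one_compartment", cl_cen = cl, v_cen = v, ...)
}

# Independent ODE oracle for linear compartment systems (numerical, via
# deSolve with default settings; independent of the eigen-based closed forms).
ode_oracle <- function(A, b_input, input_fn, times, y0 = NULL) {
  if (is.null(y0)) y0 <- numeric(nrow(A))
  f <- function(t, y, p) list(as.vector(A %*% y) + b_input * input_fn(t))
  out <- deSolve::ode(y0, times, f, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  t(unname(out[, -1, drop = FALSE]))
}

# Independent matrix-exponential propagator (scaling-and-squaring Pade),
# used as an oracle against lsoda-based simulation.
expm_pade <- function(M) {
  n <- nrow(M)
  s <- max(0, ceiling(log2(max(1, norm(M, "I")))))
  Ms <- M / 2^s
  X <- diag(n); E <- diag(n); fac <- 1
  term <- diag(n)
  for (k in 1:12) {
    term <- term %*% Ms / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# One bolus-dose study spec used across CNS-level tests.
mtx_spec <- function(ppa = 14, kpuu = 0.114) {
  cns_model_spec(drug_mtx(), rat_phys(), load_plasma_model("mtx_rg2"),
                 ppa_correction = ppa, kpuu_ecf_target = kpuu)
}

probe_base <- function(pm = NULL) {
  if (is.null(pm)) {
    pm <- load_plasma_model("let_c6")
    pm$sigma_prop <- 0.15; pm$sigma_add <- 0
    pm$omega_cl <- 0; pm$omega_v <- 0
  }
  cns_model_spec(drug_probe(), rat_phys(), pm, ppa_correction = 1,
                 kpuu_ecf_target = 0.1)
}
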