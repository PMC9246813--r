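#' Blood-tumor-barrier fold changes
#'
#' The two estimated BTB pathophysiology parameters, expressed as fold changes
#' over the control-brain BBB: `f_pore` scales the paracellular clearance
#' (via the pore areal fraction; > 0) and `f_efflux` scales the *active*
#' transcellular clearance component beyond passive. `f_efflux = 1` preserves
#' the control active transport, 0 abolishes it, and negative values reverse
#' it to net active influx.
#'
#' @param f_pore Pore-size fold change (> 0).
#' @param f_efflux Active-efflux-clearance fold change (any real).
#' @return An object of class `fold_changes`.
#' @export
fold_changes <- function(f_pore = 1, f_efflux = 1) {
  if (!is.finite(f_pore) || f_pore <= 0) stop("'f_pore' must be positive")
  if (!is.finite(f_efflux)) stop("'f_efflux' must be finite")
  structure(list(f_pore = f_pore, f_efflux = f_efflux), class = "fold_changes")
}

#' Tumor model specification
#'
#' A fully resolved control-brain model plus a tumor pathophysiology record
#' and the BTB fold changes; simulatable as a 14-compartment system in which
#' five tumor compartments (microvascular plasma, ECF, ICF, cell membrane,
#' lysosomes) are inserted between plasma and the lateral-ventricle CSF
#' compartment. No transport between tumor ECF and brain ECF is assumed.
#'
#' @param base A [cns_model_spec] (control brain, including the paracellular
#'   correction and Kp_uu-derived asymmetry factors).
#' @param tumor A [tumor_pathophysiology]; completed with healthy defaults from
#'   the base physiology.
#' @param folds A [fold_changes] object.
#' @return An object of class `tumor_model_spec`.
#' @export
tumor_model_spec <- function(base, tumor, folds = fold_changes()) {
  stopifnot(inherits(base, "cns_model_spec"),
            inherits(tumor, "tumor_pathophysiology"),
            inherits(folds, "fold_changes"))
  tumor <- fill_healthy_defaults(tumor, base$physiology)
  structure(list(base = base, tumor = tumor, folds = folds),
            class = "tumor_model_spec")
}

#' @export
print.tumor_model_spec <- function(x, ...) {
  cat("<tumor_model_spec> ", x$base$drug$name, " / ", x$tumor$model_name,
      sprintf(" (f_pore %.4g, f_efflux %.4g)\n", x$folds$f_pore,
              x$folds$f_efflux), sep = "")
  invisible(x)
}

# Passive BTB clearance set (asymmetry factors 1) for a completed tumor record.
btb_passive_clearances <- function(base, tumor) {
  drug <- base$drug; phys <- base$physiology; cst <- base$constants
  vols <- tissue_volumes(tumor$tumor_volume, tumor$f_mv, tumor$f_ecf,
                         tumor$f_mem, tumor$f_lyso)
  sa_btb <- btb_surface_area(phys$sa_bbb, vols$mv,
                             phys$brain_volume * phys$f_mv / 100)
  btb <- barrier_clearances(drug, sa_btb, phys$bbb_width,
                            phys$pore_fraction_base, base$ppa_correction,
                            tumor$ph_mv, tumor$ph_ecf, cst)
  p0 <- transmembrane_permeability(drug$logp, cst)
  sa_cell <- 3 * vols$icf / tumor$cell_radius
  cl_wo <- p0 * sa_cell * 60
  cl <- list(
    drug = drug$name,
    cl_para = btb$cl_para, cl_tc_in = btb$cl_tc_in, cl_tc_out = btb$cl_tc_out,
    cl_ecf_bulk = tumor$q_ecf_bulk_per_ml * tumor$tumor_volume * (1 - tumor$f_mv / 100),
    q_cbf = tumor$cbf * tumor$tumor_volume,
    cl_wo = cl_wo, cl_ow = cl_wo / 10^drug$logp,
    cl_lyso = p0 * sa_cell * tumor$lyso_sa_factor * 60,
    phf_ecf = ph_factor(drug, tumor$ph_ecf),
    phf_icf = ph_factor(drug, tumor$ph_icf),
    phf_lyso = ph_factor(drug, tumor$ph_lyso),
    volumes = c(mv = vols$mv, ecf = vols$ecf, icf = vols$icf,
                mem = vols$mem, lyso = vols$lyso),
    af_in = 1, af_out = 1, cl_act_in = 0, cl_act_out = 0)
  class(cl) <- "clearance_set"
  cl
}

#' Apply BTB fold changes to a passive barrier clearance set
#'
#' The pore-size fold change scales the paracellular clearance (linearly under
#' the default slit-pore reading of the areal fraction; quadratically when
#' `pore_scaling = "quadratic"` in the spec constants). The efflux fold change
#' scales the active transcellular component beyond passive,
#' `A = (AF - 1) * CL_tc`, of the control BBB (evaluated with the BTB's own
#' passive clearances): the scaled component adds to the outward clearance
#' when non-negative and its magnitude adds to the inward clearance when
#' negative (net active influx). The symmetric rule applies when the control
#' barrier carries net active influx.
#'
#' @param btb A passive `clearance_set` for the BTB (asymmetry factors 1).
#' @param control_afs Named vector `c(af_in, af_out)` of the control BBB.
#' @param folds A [fold_changes] object.
#' @param constants Transport constants carrying `pore_scaling`.
#' @return The modified `clearance_set` with `cl_act_in` / `cl_act_out` set.
#' @export
apply_fold_changes <- function(btb, control_afs, folds,
                               constants = transport_constants()) {
  stopifnot(inherits(btb, "clearance_set"), inherits(folds, "fold_changes"))
  if (btb$af_in != 1 || btb$af_out != 1)
    stop("'btb' must be a passive clearance set (asymmetry factors 1)")
  pw <- if (constants$pore_scaling == "quadratic") 2 else 1
  btb$cl_para <- btb$cl_para * folds$f_pore^pw
  a_out <- folds$f_efflux * (control_afs[["af_out"]] - 1) * btb$cl_tc_out
  a_in <- folds$f_efflux * (control_afs[["af_in"]] - 1) * btb$cl_tc_in
  btb$cl_act_out <- max(a_out, 0) + max(-a_in, 0)
  btb$cl_act_in <- max(a_in, 0) + max(-a_out, 0)
  if (barrier_outflow(btb) <= 0)
    stop("fold changes yield a non-positive total outward clearance")
  btb$af_out <- 1 + btb$cl_act_out / btb$cl_tc_out
  btb$af_in <- 1 + btb$cl_act_in / btb$cl_tc_in
  btb
}

#' Assemble the 14-compartment tumor-extended system
#'
#' Builds the control-brain clearance network, the fold-adjusted BTB clearance
#' network, and the joint linear system (rate matrix and plasma-input vector)
#' of the tumor-extended model. Tumor ECF bulk flow drains into the
#' lateral-ventricle CSF compartment; there is no tumor-ECF to brain-ECF edge.
#'
#' @param spec A [tumor_model_spec].
#' @return A list with elements `control` and `btb` (clearance sets), `A`,
#'   `b`, `state_names`, `volumes`.
#' @export
extend_with_tumor <- function(spec) {
  stopifnot(inherits(spec, "tumor_model_spec"))
  control <- build_clearances(spec$base)
  btb <- btb_passive_clearances(spec$base, spec$tumor)
  btb <- apply_fold_changes(btb, c(af_in = control$af_in, af_out = control$af_out),
                            spec$folds, spec$base$constants)
  sys <- assemble_system_matrices(control, btb)
  c(list(control = control, btb = btb), sys)
}

# Build A (rate matrix on amounts) and b (plasma-input coefficients) for the
# control system, optionally extended with tumor compartments.
assemble_system_matrices <- function(cl, btb = NULL) {
  states <- c("brain_mv", "brain_ecf", "brain_icf", "brain_mem", "brain_lyso",
              "csf_lv", "csf_tfv", "csf_cm", "csf_sas")
  vols <- unname(cl$volumes[c("mv", "ecf", "icf", "mem", "lyso",
                              "lv", "tfv", "cm", "sas")])
  if (!is.null(btb)) {
    states <- c(states, "tumor_mv", "tumor_ecf", "tumor_icf", "tumor_mem",
                "tumor_lyso")
    vols <- c(vols, unname(btb$volumes[c("mv", "ecf", "icf", "mem", "lyso")]))
  }
  n_obs <- length(states)
  states <- c(states, "cum_in", "cum_out")
  n <- length(states)
  A <- matrix(0, n, n, dimnames = list(states, states))
  V <- c(vols, 1, 1)
  idx <- function(nm) match(nm, states)
  flow <- function(from, to, clv) {
    i <- idx(from); j <- idx(to)
    A[i, i] <<- A[i, i] - clv / V[i]
    A[j, i] <<- A[j, i] + clv / V[i]
  }
  leave <- function(from, clv) flow(from, "cum_out", clv)

  leave("brain_mv", cl$q_cbf)
  flow("brain_mv", "brain_ecf", barrier_inflow(cl))
  flow("brain_ecf", "brain_mv", barrier_outflow(cl))
  half_in <- 0.5 * (cl$cl_para_bcsfb + cl$cl_tc_in_bcsfb)
  half_out <- 0.5 * (cl$cl_para_bcsfb + cl$cl_tc_out_bcsfb)
  flow("brain_mv", "csf_lv", half_in);  flow("csf_lv", "brain_mv", half_out)
  flow("brain_mv", "csf_tfv", half_in); flow("csf_tfv", "brain_mv", half_out)
  flow("brain_ecf", "csf_lv", cl$cl_ecf_bulk)
  flow("brain_ecf", "brain_mem", cl$cl_wo * cl$phf_ecf)
  flow("brain_mem", "brain_ecf", cl$cl_ow)
  flow("brain_icf", "brain_mem", cl$cl_wo * cl$phf_icf)
  flow("brain_mem", "brain_icf", cl$cl_ow)
  flow("brain_icf", "brain_lyso", cl$cl_lyso * cl$phf_icf)
  flow("brain_lyso", "brain_icf", cl$cl_lyso * cl$phf_lyso)
  flow("csf_lv", "csf_tfv", cl$q_csf)
  flow("csf_tfv", "csf_cm", cl$q_csf)
  flow("csf_cm", "csf_sas", cl$q_csf)
  leave("csf_sas", cl$q_csf)

  b <- numeric(n)
  b[idx("brain_mv")] <- cl$q_cbf
  if (!is.null(btb)) {
    leave("tumor_mv", btb$q_cbf)
    flow("tumor_mv", "tumor_ecf", barrier_inflow(btb))
    flow("tumor_ecf", "tumor_mv", barrier_outflow(btb))
    flow("tumor_ecf", "csf_lv", btb$cl_ecf_bulk)
    flow("tumor_ecf", "tumor_mem", btb$cl_wo * btb$phf_ecf)
    flow("tumor_mem", "tumor_ecf", btb$cl_ow)
    flow("tumor_icf", "tumor_mem", btb$cl_wo * btb$phf_icf)
    flow("tumor_mem", "tumor_icf", btb$cl_ow)
    flow("tumor_icf", "tumor_lyso", btb$cl_lyso * btb$phf_icf)
    flow("tumor_lyso", "tumor_icf", btb$cl_lyso * btb$phf_lyso)
    b[idx("tumor_mv")] <- btb$q_cbf
  }
  b[idx("cum_in")] <- sum(b)
  list(A = A, b = b, state_names = states, volumes = V, n_obs = n_obs)
}

# Tumor-only subsystem (exact for tumor compartments: the rest of the CNS
# never feeds back into them). Used as a fast path for tumor-ECF objectives.
assemble_tumor_subsystem <- function(spec) {
  control <- build_clearances(spec$base)
  btb <- btb_passive_clearances(spec$base, spec$tumor)
  btb <- apply_fold_changes(btb, c(af_in = control$af_in, af_out = control$af_out),
                            spec$folds, spec$base$constants)
  c(tumor_subsystem_matrices(btb), list(control = control, btb = btb))
}

# Rate matrix of the 5 tumor states for a fold-applied BTB clearance set.
tumor_subsystem_matrices <- function(btb) {
  states <- c("tumor_mv", "tumor_ecf", "tumor_icf", "tumor_mem", "tumor_lyso")
  V <- unname(btb$volumes[c("mv", "ecf", "icf", "mem", "lyso")])
  n <- 5L
  A <- matrix(0, n, n, dimnames = list(states, states))
  flow <- function(i, j, clv) {
    A[i, i] <<- A[i, i] - clv / V[i]
    if (j > 0) A[j, i] <<- A[j, i] + clv / V[i]
  }
  flow(1L, 0L, btb$q_cbf)
  flow(1L, 2L, barrier_inflow(btb)); flow(2L, 1L, barrier_outflow(btb))
  flow(2L, 0L, btb$cl_ecf_bulk)
  flow(2L, 4L, btb$cl_wo * btb$phf_ecf); flow(4L, 2L, btb$cl_ow)
  flow(3L, 4L, btb$cl_wo * btb$phf_icf); flow(4L, 3L, btb$cl_ow)
  flow(3L, 5L, btb$cl_lyso * btb$phf_icf); flow(5L, 3L, btb$cl_lyso * btb$phf_lyso)
  b <- numeric(n); b[1] <- btb$q_cbf
  list(A = A, b = b, state_names = states, volumes = V, n_obs = n)
}

# Internal dispatcher: assembled linear system for either spec class.
assemble_system <- function(spec) {
  if (inherits(spec, "tumor_model_spec")) {
    extend_with_tumor(spec)
  } else {
    cl <- build_clearances(spec)
    c(list(control = cl, btb = NULL), assemble_system_matrices(cl))
  }
}

spec_plasma <- function(spec) {
  if (inherits(spec, "tumor_model_spec")) spec$base$plasma else spec$plasma
}

#' Simulate the CNS (or tumor-extended) model
#'
#' Integrates the linear mass-action system driven by the unbound plasma
#' forcing function with a stiff-capable solver (`deSolve::lsoda`) and a
#' constant analytic Jacobian. Returns unbound concentrations (ng/mL) in every
#' compartment, including the plasma forcing itself, in long format. A
#' whole-system mass-balance table (drug in the CNS plus cumulative outflow
#' versus cumulative inflow) is attached as `attr(, "mass_balance")`.
#'
#' @param spec A [cns_model_spec] or [tumor_model_spec].
#' @param doses A [dose_event] or list of them (driving the plasma model).
#' @param times Sorted output times (min); 0 is prepended if absent.
#' @param eta Optional named plasma IIV deviations `c(cl = , v = )`.
#' @param plasma_fn Optional replacement forcing function returning *unbound*
#'   plasma concentration (ng/mL) as a function of time; overrides the
#'   empirical plasma model (used e.g. for constant-infusion steady-state
#'   checks).
#' @param rtol,atol Integrator tolerances.
#' @return A long data.frame (`time_min`, `compartment`, `conc_ng_per_ml`)
#'   with attributes `amounts` (state matrix, ug) and `mass_balance`.
#' @export
simulate_cns <- function(spec, doses = NULL, times, eta = NULL,
                         plasma_fn = NULL, rtol = 1e-8, atol = 1e-10) {
  if (is.unsorted(times)) stop("'times' must be sorted")
  sys <- assemble_system(spec)
  pm <- spec_plasma(spec)
  if (is.null(plasma_fn)) {
    if (is.null(doses)) stop("'doses' required when no 'plasma_fn' is given")
    pf <- plasma_conc_fn(pm, doses, eta)
    fscale <- pm$fup_scale
    cp_u <- function(t) pf(t) * fscale / 1000  # unbound ug/mL
  } else {
    cp_u <- function(t) plasma_fn(t) / 1000
  }
  tt <- times
  if (tt[1] > 0) tt <- c(0, tt)
  A <- sys$A; b <- sys$b
  deriv <- function(t, y, p) list(as.vector(A %*% y) + b * cp_u(t))
  jac <- function(t, y, p) A
  out <- deSolve::lsoda(y = numeric(length(sys$state_names)), times = tt,
                        func = deriv, parms = NULL, jacfunc = jac,
                        jactype = "fullusr", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("CNS integration failed (istate ", attr(out, "istate")[1],
         ", rtol ", rtol, ", atol ", atol, ")")
  amounts <- t(unname(out[, -1, drop = FALSE]))
  rownames(amounts) <- sys$state_names
  keep <- match(times, tt)
  amounts <- amounts[, keep, drop = FALSE]

  n_obs <- sys$n_obs
  conc <- 1000 * amounts[seq_len(n_obs), , drop = FALSE] /
    sys$volumes[seq_len(n_obs)]
  plasma_conc <- cp_u(times) * 1000
  res <- data.frame(
    time_min = rep(times, n_obs + 1L),
    compartment = rep(c("plasma", sys$state_names[seq_len(n_obs)]),
                      each = length(times)),
    conc_ng_per_ml = c(plasma_conc, as.vector(t(conc))))
  in_system <- colSums(amounts[seq_len(n_obs), , drop = FALSE])
  cum_in <- amounts["cum_in", ]
  cum_out <- amounts["cum_out", ]
  mb <- data.frame(time_min = times, in_system = in_system, cum_in = cum_in,
                   cum_out = cum_out,
                   rel_error = (cum_in - cum_out - in_system) /
                     pmax(cum_in, .Machine$double.eps))
  attr(res, "amounts") <- amounts
  attr(res, "mass_balance") <- mb
  attr(res, "clearances") <- sys[c("control", "btb")]
  res
}
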