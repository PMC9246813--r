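#' CNS model specification
#'
#' Bundles a drug record, species physiology and plasma forcing model into a
#' simulatable nine-compartment CNS model spec. Asymmetry factors (AF) on the
#' transcellular BBB clearances can be given directly or derived from a
#' measured steady-state unbound ECF partition coefficient
#' (`kpuu_ecf_target`); when a target is given the AFs are (re)computed at
#' clearance-build time, so they stay consistent with the current paracellular
#' correction factor.
#'
#' @param drug A [drug_properties] object.
#' @param physiology A [cns_physiology] object.
#' @param plasma A [plasma_pk_model] object.
#' @param ppa_correction Paracellular-permeability correction factor
#'   (fold-decrease, > 0) applied as a divisor on the paracellular BBB
#'   clearance.
#' @param kpuu_ecf_target Optional measured Kp_uu,ECF used to set the AFs.
#' @param af_in,af_out Asymmetry factors (>= 1; at most one may exceed 1).
#'   Ignored when `kpuu_ecf_target` is given.
#' @param constants Transport correlation constants, see
#'   [transport_constants()].
#' @return An object of class `cns_model_spec`.
#' @export
cns_model_spec <- function(drug, physiology, plasma, ppa_correction = 1,
                           kpuu_ecf_target = NULL, af_in = 1, af_out = 1,
                           constants = transport_constants()) {
  stopifnot(inherits(drug, "drug_properties"),
            inherits(physiology, "cns_physiology"),
            inherits(plasma, "plasma_pk_model"))
  if (!is.finite(ppa_correction) || ppa_correction <= 0)
    stop("'ppa_correction' must be positive")
  if (af_in < 1 || af_out < 1) stop("asymmetry factors must be >= 1")
  if (af_in > 1 && af_out > 1)
    stop("at most one of 'af_in', 'af_out' may exceed 1")
  if (!is.null(kpuu_ecf_target) &&
      (!is.finite(kpuu_ecf_target) || kpuu_ecf_target <= 0))
    stop("'kpuu_ecf_target' must be positive")
  structure(list(drug = drug, physiology = physiology, plasma = plasma,
                 ppa_correction = ppa_correction,
                 kpuu_ecf_target = kpuu_ecf_target,
                 af_in = af_in, af_out = af_out, constants = constants),
            class = "cns_model_spec")
}

#' @export
print.cns_model_spec <- function(x, ...) {
  cat("<cns_model_spec> ", x$drug$name, " / ", x$physiology$species,
      " (PPA correction ", x$ppa_correction, ")\n", sep = "")
  invisible(x)
}

# Compartment volumes (mL) implied by a physiology-like parameter set.
tissue_volumes <- function(total_volume, f_mv, f_ecf, f_mem, f_lyso) {
  f_icf <- 100 - f_mv - f_ecf - f_mem - f_lyso
  if (f_icf <= 0) stop("volume fractions leave no ICF volume")
  list(mv = total_volume * f_mv / 100, ecf = total_volume * f_ecf / 100,
       icf = total_volume * f_icf / 100, mem = total_volume * f_mem / 100,
       lyso = total_volume * f_lyso / 100)
}

# Barrier + tissue clearances shared by the BBB and the BTB.
# 'sa' is the barrier surface area; pH values and volumes are donor-side
# specific. All permeabilities (cm/s) convert to mL/min via area (cm^2) * 60.
barrier_clearances <- function(drug, sa, bbb_width, pore_fraction, ppa_correction,
                               ph_mv, ph_ecf, constants) {
  d_aq <- aqueous_diffusivity(drug$mw, constants)
  p0 <- transmembrane_permeability(drug$logp, constants)
  list(cl_para = (d_aq / bbb_width) * sa * pore_fraction * 60 / ppa_correction,
       cl_tc_in = p0 * sa * 60 * ph_factor(drug, ph_mv),
       cl_tc_out = p0 * sa * 60 * ph_factor(drug, ph_ecf))
}

#' Assemble the clearance network of the CNS model
#'
#' Computes every clearance of the nine-compartment model from the drug record
#' and physiology: paracellular and transcellular BBB/BCSFB clearances with
#' donor-side pH factors, ECF bulk flow, perfusion, CSF flow, cell-membrane
#' exchange (water-to-lipid and lipid-to-water) and lysosomal exchange with pH
#' trapping. When the spec carries `kpuu_ecf_target` the asymmetry factors are
#' derived here via [af_from_kpuu()], consistently with the current
#' paracellular correction.
#'
#' @param spec A [cns_model_spec].
#' @return An object of class `clearance_set`: clearances in mL/min plus the
#'   compartment volumes (mL) and the resolved asymmetry factors.
#' @export
build_clearances <- function(spec) {
  stopifnot(inherits(spec, "cns_model_spec"))
  drug <- spec$drug; phys <- spec$physiology; cst <- spec$constants
  vols <- tissue_volumes(phys$brain_volume, phys$f_mv, phys$f_ecf,
                         phys$f_mem, phys$f_lyso)
  bbb <- barrier_clearances(drug, phys$sa_bbb, phys$bbb_width,
                            phys$pore_fraction_base, spec$ppa_correction,
                            phys$ph_mv, phys$ph_ecf, cst)
  # BCSFB: same relations with its own surface area; the paracellular
  # correction factor is a BBB property and is not applied here.
  bcsfb <- barrier_clearances(drug, phys$sa_bcsfb, phys$bbb_width,
                              phys$pore_fraction_base, 1,
                              phys$ph_mv, phys$ph_ecf, cst)
  p0 <- transmembrane_permeability(drug$logp, cst)
  sa_cell <- 3 * vols$icf / phys$cell_radius      # sphere pack: SA = 3V/r
  k_mem <- 10^drug$logp                           # membrane/water partition
  cl_wo <- p0 * sa_cell * 60                      # water->lipid, before PHF
  cl_ow <- cl_wo / k_mem                          # lipid->water
  cl_lyso <- p0 * sa_cell * phys$lyso_sa_factor * 60

  cl <- list(
    drug = drug$name,
    cl_para = bbb$cl_para, cl_tc_in = bbb$cl_tc_in, cl_tc_out = bbb$cl_tc_out,
    cl_para_bcsfb = bcsfb$cl_para, cl_tc_in_bcsfb = bcsfb$cl_tc_in,
    cl_tc_out_bcsfb = bcsfb$cl_tc_out,
    cl_ecf_bulk = phys$q_ecf_bulk_per_ml * phys$brain_volume * (1 - phys$f_mv / 100),
    q_cbf = phys$cbf * phys$brain_volume,         # density pinned at 1 g/mL
    q_csf = phys$q_csf,
    cl_wo = cl_wo, cl_ow = cl_ow, cl_lyso = cl_lyso,
    phf_ecf = ph_factor(drug, phys$ph_ecf),
    phf_icf = ph_factor(drug, phys$ph_icf),
    phf_lyso = ph_factor(drug, phys$ph_lyso),
    volumes = c(mv = vols$mv, ecf = vols$ecf, icf = vols$icf, mem = vols$mem,
                lyso = vols$lyso, lv = phys$v_lv, tfv = phys$v_tfv,
                cm = phys$v_cm, sas = phys$v_sas),
    af_in = spec$af_in, af_out = spec$af_out,
    cl_act_in = 0, cl_act_out = 0)
  class(cl) <- "clearance_set"
  if (!is.null(spec$kpuu_ecf_target)) {
    afs <- af_from_kpuu(spec$kpuu_ecf_target, cl)
    cl$af_in <- afs[["af_in"]]; cl$af_out <- afs[["af_out"]]
  }
  cl$cl_act_in <- (cl$af_in - 1) * cl$cl_tc_in
  cl$cl_act_out <- (cl$af_out - 1) * cl$cl_tc_out
  cl
}

#' @export
print.clearance_set <- function(x, ...) {
  cat("<clearance_set> ", x$drug, "\n", sep = "")
  cat(sprintf("  BBB: CL_para %.4g, CL_tc,in %.4g, CL_tc,out %.4g mL/min\n",
              x$cl_para, x$cl_tc_in, x$cl_tc_out))
  cat(sprintf("  AF_in %.4g, AF_out %.4g; ECF bulk %.4g, CBF %.4g mL/min\n",
              x$af_in, x$af_out, x$cl_ecf_bulk, x$q_cbf))
  invisible(x)
}

# Total inward / outward BBB (or BTB) clearances seen by the ECF compartment.
barrier_inflow <- function(cl) cl$cl_para + cl$cl_tc_in + cl$cl_act_in
barrier_outflow <- function(cl) cl$cl_para + cl$cl_tc_out + cl$cl_act_out

#' Steady-state unbound ECF partition coefficient
#'
#' Closed form for the ratio of unbound ECF to unbound plasma concentration at
#' steady state: inward barrier clearance over outward barrier clearance plus
#' ECF bulk flow. The membrane, intracellular and lysosomal sub-compartments
#' form a dead-end chain whose fluxes cancel at steady state and therefore do
#' not appear.
#'
#' @param clearances A `clearance_set` from [build_clearances()].
#' @return Kp_uu,ECF (dimensionless).
#' @export
steady_state_kpuu <- function(clearances) {
  den <- barrier_outflow(clearances) + clearances$cl_ecf_bulk
  if (!is.finite(den) || den <= 0) stop("non-positive outflow denominator")
  barrier_inflow(clearances) / den
}

#' Asymmetry factors from a measured Kp_uu,ECF
#'
#' Inverts the steady-state closed form: when the measured partition
#' coefficient is below the passive prediction, net active efflux is implied
#' (`af_in = 1`, `af_out` solves the equation); above it, net active influx
#' (`af_out = 1`). The solution is unique and closed-form, and round-trips
#' through [steady_state_kpuu()].
#'
#' @param kpuu_measured Measured Kp_uu,ECF (> 0).
#' @param clearances A passive `clearance_set` (asymmetry factors 1).
#' @return Named vector `c(af_in, af_out)`.
#' @export
af_from_kpuu <- function(kpuu_measured, clearances) {
  if (!is.finite(kpuu_measured) || kpuu_measured <= 0)
    stop("'kpuu_measured' must be positive")
  cl <- clearances
  passive <- (cl$cl_para + cl$cl_tc_in) /
    (cl$cl_para + cl$cl_tc_out + cl$cl_ecf_bulk)
  if (kpuu_measured <= passive) {
    af_out <- ((cl$cl_para + cl$cl_tc_in) / kpuu_measured -
               cl$cl_para - cl$cl_ecf_bulk) / cl$cl_tc_out
    af_in <- 1
  } else {
    af_in <- (kpuu_measured * (cl$cl_para + cl$cl_tc_out + cl$cl_ecf_bulk) -
              cl$cl_para) / cl$cl_tc_in
    af_out <- 1
  }
  if (!is.finite(af_in) || !is.finite(af_out) || af_in < 1 - 1e-9 || af_out < 1 - 1e-9)
    stop("measured Kp_uu,ECF is inconsistent with the passive clearances")
  c(af_in = max(af_in, 1), af_out = max(af_out, 1))
}
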