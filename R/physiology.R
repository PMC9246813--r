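#' Round to significant figures, halves away from zero
#'
#' Published parameter tables round half-values away from zero (e.g. the mean
#' of 6.86 and 6.75, exactly 6.805, prints as 6.81). Base `signif()` rounds
#' half to even, so derived values are rounded with this helper instead. A tiny
#' epsilon guards against binary representation error in exact decimal halves.
#'
#' @param x Numeric vector.
#' @param sig_figs Number of significant figures (default 3).
#' @return Rounded numeric vector.
#' @export
signif_half_up <- function(x, sig_figs = 3) {
  stopifnot(sig_figs >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  mag <- floor(log10(abs(x[nz])))
  scale <- 10^(sig_figs - 1 - mag)
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * scale + 0.5 + 1e-9) / scale
  out
}

#' Species-level CNS physiology
#'
#' Container for the volumes, flows, surface areas and pH values of the healthy
#' CNS that parameterize the nine-compartment model. The printed species rows
#' (volume fractions, pH, blood flow) follow the published healthy-brain
#' values; absolute surface areas, CSF volumes/flows, membrane geometry and the
#' microvascular/lysosomal pH are companion-model-style fixtures shipped as
#' versioned defaults in [default_physiology()].
#'
#' @param species `"rat"` or `"human"`.
#' @param brain_volume Brain volume (mL).
#' @param f_mv,f_ecf,f_mem,f_lyso Volume fractions (% of brain volume) of
#'   microvasculature, ECF, cell membrane and lysosomes. The ICF fraction is
#'   the remainder to 100%.
#' @param cbf Cerebral blood flow (mL/min/g); tissue density is pinned at
#'   1 g/mL so `cbf * brain_volume` is the volumetric perfusion.
#' @param q_ecf_bulk_per_ml ECF bulk flow per mL tissue (mL/min/mL).
#' @param q_csf CSF production flow (mL/min).
#' @param sa_bbb,sa_bcsfb Surface areas of the BBB and BCSFB (cm^2).
#' @param bbb_width Thickness of the barrier (cm).
#' @param pore_fraction_base Areal fraction of the paracellular pathway at the
#'   base pore size.
#' @param pore_radius_base Base paracellular pore radius (nm).
#' @param ph_mv,ph_ecf,ph_icf,ph_lyso Compartment pH values.
#' @param cell_radius Parenchymal cell radius (cm).
#' @param lyso_sa_factor Lysosomal surface area as a multiple of the total cell
#'   surface area.
#' @param v_lv,v_tfv,v_cm,v_sas CSF compartment volumes (mL): lateral
#'   ventricles, third+fourth ventricles, cisterna magna, subarachnoid space.
#' @return An object of class `cns_physiology`.
#' @export
cns_physiology <- function(species, brain_volume, f_mv, f_ecf, f_mem, f_lyso,
                           cbf, q_ecf_bulk_per_ml, q_csf, sa_bbb, sa_bcsfb,
                           bbb_width, pore_fraction_base, pore_radius_base,
                           ph_mv, ph_ecf, ph_icf, ph_lyso, cell_radius,
                           lyso_sa_factor, v_lv, v_tfv, v_cm, v_sas) {
  out <- list(species = species, brain_volume = brain_volume, f_mv = f_mv,
              f_ecf = f_ecf, f_mem = f_mem, f_lyso = f_lyso, cbf = cbf,
              q_ecf_bulk_per_ml = q_ecf_bulk_per_ml, q_csf = q_csf,
              sa_bbb = sa_bbb, sa_bcsfb = sa_bcsfb, bbb_width = bbb_width,
              pore_fraction_base = pore_fraction_base,
              pore_radius_base = pore_radius_base, ph_mv = ph_mv,
              ph_ecf = ph_ecf, ph_icf = ph_icf, ph_lyso = ph_lyso,
              cell_radius = cell_radius, lyso_sa_factor = lyso_sa_factor,
              v_lv = v_lv, v_tfv = v_tfv, v_cm = v_cm, v_sas = v_sas)
  validate_physiology(out)
  class(out) <- "cns_physiology"
  out
}

validate_physiology <- function(p) {
  pos <- c("brain_volume", "cbf", "q_ecf_bulk_per_ml", "q_csf", "sa_bbb",
           "sa_bcsfb", "bbb_width", "pore_fraction_base", "pore_radius_base",
           "cell_radius", "lyso_sa_factor", "v_lv", "v_tfv", "v_cm", "v_sas")
  for (f in pos) {
    v <- p[[f]]
    if (is.null(v) || !is.finite(v) || v <= 0)
      stop("physiology field '", f, "' must be positive")
  }
  for (f in c("f_mv", "f_ecf", "f_mem", "f_lyso")) {
    v <- p[[f]]
    if (is.null(v) || !is.finite(v) || v <= 0 || v >= 100)
      stop("physiology fraction '", f, "' must be in (0, 100) %")
  }
  if (sum(p$f_mv, p$f_ecf, p$f_mem, p$f_lyso) >= 100)
    stop("volume fractions exceed 100%")
  for (f in c("ph_mv", "ph_ecf", "ph_icf", "ph_lyso")) {
    v <- p[[f]]
    if (is.null(v) || !is.finite(v) || v < 0 || v > 14)
      stop("physiology pH '", f, "' must be in [0, 14]")
  }
  invisible(p)
}

#' Default healthy CNS physiology
#'
#' Pinned healthy-brain parameter sets. Printed species values: rat f_MV 3.00%,
#' f_ECF 20.0%, pH ECF/ICF 7.30/7.00, CBF 1.53 mL/min/g; human f_MV 3.67%,
#' f_ECF 20.0%, CBF 0.527 mL/min/g. The remaining fields are versioned
#' fixtures (see the methods vignette).
#'
#' @param species `"rat"` or `"human"`.
#' @return A [cns_physiology] object.
#' @export
default_physiology <- function(species = c("rat", "human")) {
  species <- match.arg(species)
  if (species == "rat") {
    cns_physiology("rat", brain_volume = 1.8, f_mv = 3.00, f_ecf = 20.0,
                   f_mem = 0.33, f_lyso = 1.0, cbf = 1.53,
                   q_ecf_bulk_per_ml = 1.1e-4, q_csf = 0.0022,
                   sa_bbb = 263, sa_bcsfb = 25, bbb_width = 0.5e-4,
                   pore_fraction_base = 1e-4, pore_radius_base = 0.7,
                   ph_mv = 7.4, ph_ecf = 7.30, ph_icf = 7.00, ph_lyso = 5.0,
                   cell_radius = 5e-4, lyso_sa_factor = 1,
                   v_lv = 0.05, v_tfv = 0.05, v_cm = 0.017, v_sas = 0.18)
  } else {
    cns_physiology("human", brain_volume = 1400, f_mv = 3.67, f_ecf = 20.0,
                   f_mem = 0.33, f_lyso = 1.0, cbf = 0.527,
                   q_ecf_bulk_per_ml = 1.25e-4, q_csf = 0.35,
                   sa_bbb = 1.5e5, sa_bcsfb = 1.5e4, bbb_width = 0.5e-4,
                   pore_fraction_base = 1e-4, pore_radius_base = 0.7,
                   ph_mv = 7.4, ph_ecf = 7.30, ph_icf = 7.00, ph_lyso = 5.0,
                   cell_radius = 5e-4, lyso_sa_factor = 1,
                   v_lv = 22.5, v_tfv = 2.8, v_cm = 7.5, v_sas = 90)
  }
}

#' Tumor pathophysiology record
#'
#' Tumor-specific volumes, fractions, pH values and blood flow. Fields not
#' supplied here are inherited from the paired healthy physiology by
#' [fill_healthy_defaults()] (microvascular and lysosomal pH, membrane and
#' lysosome fractions, ECF bulk flow per mL, cell radius), reflecting the
#' assumption that these are unchanged in tumor tissue.
#'
#' @param model_name Tumor model or patient identifier.
#' @param tumor_volume Tumor volume (mL).
#' @param f_mv,f_ecf Volume fractions (%).
#' @param ph_ecf,ph_icf Extracellular and intracellular pH.
#' @param cbf Tumor blood flow (mL/min/g).
#' @param ... Optional overrides for inherited fields (`ph_mv`, `ph_lyso`,
#'   `f_mem`, `f_lyso`, `q_ecf_bulk_per_ml`, `cell_radius`, `lyso_sa_factor`).
#' @return An object of class `tumor_pathophysiology`.
#' @export
tumor_pathophysiology <- function(model_name, tumor_volume, f_mv, f_ecf,
                                  ph_ecf, ph_icf, cbf, ...) {
  extra <- list(...)
  allowed <- c("ph_mv", "ph_lyso", "f_mem", "f_lyso", "q_ecf_bulk_per_ml",
               "cell_radius", "lyso_sa_factor")
  bad <- setdiff(names(extra), allowed)
  if (length(bad)) stop("unknown tumor fields: ", paste(bad, collapse = ", "))
  out <- c(list(model_name = model_name, tumor_volume = tumor_volume,
                f_mv = f_mv, f_ecf = f_ecf, ph_ecf = ph_ecf, ph_icf = ph_icf,
                cbf = cbf), extra)
  stopifnot(tumor_volume > 0, f_mv > 0, f_mv < 100, f_ecf > 0, f_ecf < 100,
            ph_ecf >= 0, ph_ecf <= 14, ph_icf >= 0, ph_icf <= 14, cbf > 0)
  class(out) <- "tumor_pathophysiology"
  out
}

#' Fill unspecified tumor fields from healthy physiology
#'
#' Copies every field the tumor record does not specify from the paired healthy
#' [cns_physiology]; specified fields are untouched. Idempotent.
#'
#' @param tumor A [tumor_pathophysiology] object.
#' @param healthy A [cns_physiology] object.
#' @return The completed `tumor_pathophysiology`.
#' @export
fill_healthy_defaults <- function(tumor, healthy) {
  stopifnot(inherits(tumor, "tumor_pathophysiology"),
            inherits(healthy, "cns_physiology"))
  inherit <- c("ph_mv", "ph_lyso", "f_mem", "f_lyso", "q_ecf_bulk_per_ml",
               "cell_radius", "lyso_sa_factor")
  for (f in inherit) if (is.null(tumor[[f]])) tumor[[f]] <- healthy[[f]]
  tumor
}

#' Mean of literature values, rounded as published
#'
#' Representative tumor parameters are the arithmetic mean of the literature
#' values for a model (or of similar tumor types), rounded to 3 significant
#' figures for tabulation.
#'
#' @param values Non-empty numeric vector of source values.
#' @param sig_figs Significant figures for rounding (default 3).
#' @return The rounded mean.
#' @export
#' @examples
#' derive_mean_parameter(c(5.58, 2.25))  # 3.92 (% MV)
derive_mean_parameter <- function(values, sig_figs = 3) {
  if (length(values) == 0) stop("'values' must be non-empty")
  signif_half_up(mean(values), sig_figs)
}

#' Scaled mean of literature values
#'
#' As [derive_mean_parameter()] but multiplied by a positive scale before
#' rounding (used e.g. for highly vascularized lines whose microvascular
#' density is a known multiple of the source lines).
#'
#' @inheritParams derive_mean_parameter
#' @param scale Positive multiplier.
#' @return The rounded scaled mean.
#' @export
derive_scaled_parameter <- function(values, scale, sig_figs = 3) {
  if (length(values) == 0) stop("'values' must be non-empty")
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be positive")
  signif_half_up(scale * mean(values), sig_figs)
}

#' Absolute tumor parameter from a tumor/control ratio
#'
#' Literature often reports tumor blood flow or microvascular fraction relative
#' to control brain; the absolute tumor value is the ratio multiplied by the
#' representative healthy value.
#'
#' @param relative Tumor/control ratio (> 0).
#' @param healthy_value Representative healthy value (> 0).
#' @return The product.
#' @export
absolute_from_relative_cbf <- function(relative, healthy_value) {
  if (any(!is.finite(relative)) || any(relative <= 0))
    stop("'relative' must be positive")
  if (any(!is.finite(healthy_value)) || any(healthy_value <= 0))
    stop("'healthy_value' must be positive")
  relative * healthy_value
}

#' Blood-tumor-barrier surface area
#'
#' The BTB surface area scales the healthy BBB surface area by the ratio of
#' microvascular volumes between tumor and healthy brain.
#'
#' @param sa_bbb Healthy BBB surface area (cm^2).
#' @param v_mv_tumor Tumor microvascular volume (mL).
#' @param v_mv_brain Healthy brain microvascular volume (mL).
#' @return Surface area in cm^2, linear in `v_mv_tumor`.
#' @export
btb_surface_area <- function(sa_bbb, v_mv_tumor, v_mv_brain) {
  if (!all(is.finite(c(sa_bbb, v_mv_tumor, v_mv_brain))) ||
      sa_bbb <= 0 || v_mv_tumor <= 0 || v_mv_brain <= 0)
    stop("all surface-area inputs must be positive")
  sa_bbb * v_mv_tumor / v_mv_brain
}
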