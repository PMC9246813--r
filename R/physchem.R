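#' Drug physicochemical record
#'
#' Bundles the physicochemical identity of a compound that drives every
#' permeability term in the model: molecular weight, ionization constants,
#' lipophilicity and plasma protein binding.
#'
#' @param name Drug name (character scalar).
#' @param mw Molecular weight in g/mol; must be positive.
#' @param charge_class One of `"acid"`, `"base"`, `"neutral"`. Determines which
#'   ionization constant is used for pH partitioning; a drug is assigned a
#'   single class even when it carries both acidic and basic groups.
#' @param pka_acid Strongest acidic ionization constant (pH units). Required
#'   when `charge_class = "acid"`.
#' @param pkb_base Strongest basic ionization constant (pH units). Required
#'   when `charge_class = "base"`.
#' @param logp Octanol-water log partition coefficient (dimensionless).
#' @param fup Fraction unbound in plasma, in (0, 1]. Defaults to 1, i.e. the
#'   plasma model is taken to describe unbound drug already.
#'
#' @return An object of class `drug_properties`.
#' @export
#' @examples
#' drug_properties("temozolomide", mw = 194.15, charge_class = "neutral",
#'                 logp = -1.153, fup = 0.85)
drug_properties <- function(name, mw, charge_class = c("neutral", "acid", "base"),
                            pka_acid = NULL, pkb_base = NULL, logp, fup = 1) {
  charge_class <- match.arg(charge_class)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0)
    stop("'mw' must be a positive number (g/mol)")
  if (!is.numeric(logp) || length(logp) != 1L || !is.finite(logp))
    stop("'logp' must be a finite number")
  if (!is.numeric(fup) || length(fup) != 1L || fup <= 0 || fup > 1)
    stop("'fup' must be in (0, 1]")
  if (charge_class == "acid" && is.null(pka_acid))
    stop("charge_class 'acid' requires 'pka_acid'")
  if (charge_class == "base" && is.null(pkb_base))
    stop("charge_class 'base' requires 'pkb_base'")
  out <- list(name = name, mw = mw, charge_class = charge_class,
              pka_acid = pka_acid, pkb_base = pkb_base, logp = logp, fup = fup)
  class(out) <- "drug_properties"
  out
}

#' @export
print.drug_properties <- function(x, ...) {
  cat("<drug_properties> ", x$name, "\n", sep = "")
  cat("  MW ", x$mw, " g/mol, ", x$charge_class,
      if (x$charge_class == "acid") paste0(" (pKa ", x$pka_acid, ")"),
      if (x$charge_class == "base") paste0(" (pKb ", x$pkb_base, ")"),
      ", logP ", x$logp, ", fup ", x$fup, "\n", sep = "")
  invisible(x)
}

#' Transport correlation constants
#'
#' Pinned default correlations used to turn a physicochemical record into
#' transport primitives. The diffusivity correlation is
#' `D = diff_coef * MW^diff_exp` (cm^2/s) and the transmembrane permeability of
#' the unionized species is `log10 P0 = perm_slope * logP + perm_intercept`
#' (cm/s). Both are declared substitutes for companion-model correlations and
#' can be overridden without code change.
#'
#' @param diff_coef,diff_exp Aqueous diffusivity correlation constants.
#' @param perm_slope,perm_intercept Transmembrane permeability relation.
#' @param pore_scaling How the paracellular clearance scales with the pore-size
#'   fold change: `"linear"` (slit-pore geometry, default) or `"quadratic"`
#'   (cylindrical pores).
#' @return A named list of constants.
#' @export
transport_constants <- function(diff_coef = 9.9e-5, diff_exp = -0.453,
                                perm_slope = 0.939, perm_intercept = -6.21,
                                pore_scaling = c("linear", "quadratic")) {
  pore_scaling <- match.arg(pore_scaling)
  list(diff_coef = diff_coef, diff_exp = diff_exp,
       perm_slope = perm_slope, perm_intercept = perm_intercept,
       pore_scaling = pore_scaling)
}

#' Fraction of drug in the unionized form at a given pH
#'
#' Monoprotic Henderson-Hasselbalch partitioning using only the ionization
#' constant relevant for the drug's charge class. Neutral drugs are unionized
#' by definition.
#'
#' @param drug A [drug_properties] object.
#' @param ph pH of the compartment, in \[0, 14\]. Vectorized.
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' mtx <- drug_properties("methotrexate", 454.45, "acid", pka_acid = 3.41,
#'                        logp = -1.85, fup = 0.448)
#' unionized_fraction(mtx, 7.30)  # ~1.29e-4
unionized_fraction <- function(drug, ph) {
  stopifnot(inherits(drug, "drug_properties"))
  if (any(!is.finite(ph)) || any(ph < 0) || any(ph > 14))
    stop("'ph' must be in [0, 14]")
  switch(drug$charge_class,
    neutral = rep(1, length(ph)),
    acid = {
      if (is.null(drug$pka_acid))
        stop("drug '", drug$name, "' is acidic but has no 'pka_acid'")
      1 / (1 + 10^(ph - drug$pka_acid))
    },
    base = {
      if (is.null(drug$pkb_base))
        stop("drug '", drug$name, "' is basic but has no 'pkb_base'")
      1 / (1 + 10^(drug$pkb_base - ph))
    })
}

#' Aqueous diffusivity of a drug
#'
#' Size-based correlation `D = diff_coef * MW^diff_exp`, strictly decreasing in
#' molecular weight.
#'
#' @param mw Molecular weight (g/mol), positive.
#' @param constants See [transport_constants()].
#' @return Diffusivity in cm^2/s.
#' @export
aqueous_diffusivity <- function(mw, constants = transport_constants()) {
  if (any(!is.finite(mw)) || any(mw <= 0)) stop("'mw' must be positive")
  constants$diff_coef * mw^constants$diff_exp
}

#' Transmembrane permeability of the unionized species
#'
#' Lipophilicity-based relation `log10 P0 = perm_slope * logP + perm_intercept`,
#' monotone increasing in logP.
#'
#' @param logp Octanol-water log partition coefficient.
#' @param constants See [transport_constants()].
#' @return Permeability in cm/s.
#' @export
transmembrane_permeability <- function(logp, constants = transport_constants()) {
  10^(constants$perm_slope * logp + constants$perm_intercept)
}

#' Donor-side pH factor
#'
#' The pH factor (PHF) multiplying transmembrane clearance on the donor side:
#' only the unionized species crosses lipid membranes, so PHF equals the
#' unionized fraction at the donor pH. Paracellular clearance is PHF-free.
#'
#' @inheritParams unionized_fraction
#' @param ph_donor Donor-compartment pH.
#' @return Multiplier in (0, 1].
#' @export
ph_factor <- function(drug, ph_donor) {
  unionized_fraction(drug, ph_donor)
}
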