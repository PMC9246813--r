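extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "btbpk")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install fallback
  if (!file.exists(p)) stop("bundled data file not found: ", file)
  p
}

#' Bundled drug physicochemical table
#'
#' Physicochemical records of the six anticancer drugs used throughout the
#' examples: molecular weight, charge class, strongest acidic/basic ionization
#' constants, logP and plasma fraction unbound (rat studies; the human
#' methotrexate fup is carried by [load_study_table()]).
#'
#' @return A data.frame, one row per drug.
#' @export
load_drug_table <- function() {
  utils::read.csv(extdata_path("drugs.csv"), stringsAsFactors = FALSE)
}

#' Fetch one bundled drug as a `drug_properties` object
#'
#' @param name Drug name as in [load_drug_table()].
#' @param fup Optional override of the bundled fraction unbound.
#' @return A [drug_properties] object.
#' @export
load_drug <- function(name, fup = NULL) {
  tab <- load_drug_table()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L)
    stop("unknown drug '", name, "'; bundled drugs: ",
         paste(tab$name, collapse = ", "))
  drug_properties(row$name, row$mw, row$charge_class,
                  pka_acid = if (is.na(row$pka_acid)) NULL else row$pka_acid,
                  pkb_base = if (is.na(row$pkb_base)) NULL else row$pkb_base,
                  logp = row$logp,
                  fup = if (!is.null(fup)) fup else if (is.na(row$fup)) 1 else row$fup)
}

#' Bundled tumor pathophysiology table
#'
#' Representative tumor parameters (volume, microvascular and ECF volume
#' fractions, extracellular/intracellular pH, blood flow) for the rat tumor
#' models and human patients analyzed in the examples.
#'
#' @return A data.frame, one row per tumor model / patient.
#' @export
load_tumor_table <- function() {
  utils::read.csv(extdata_path("tumor_models.csv"), stringsAsFactors = FALSE)
}

#' Fetch one bundled tumor model, completed with healthy defaults
#'
#' @param model_name Model name as in [load_tumor_table()].
#' @param healthy Optional [cns_physiology] used for inherited fields; defaults
#'   to the species default.
#' @return A [tumor_pathophysiology] object.
#' @export
load_tumor_model <- function(model_name, healthy = NULL) {
  tab <- load_tumor_table()
  row <- tab[tab$model_name == model_name, ]
  if (nrow(row) != 1L) stop("unknown tumor model '", model_name, "'")
  if (any(is.na(c(row$tumor_volume_ml, row$ph_icf, row$cbf_ml_min_g))))
    stop("tumor model '", model_name, "' is a source-only row (incomplete)")
  if (is.null(healthy)) healthy <- default_physiology(row$species)
  tum <- tumor_pathophysiology(row$model_name, row$tumor_volume_ml,
                               f_mv = row$f_mv_pct, f_ecf = row$f_ecf_pct,
                               ph_ecf = row$ph_ecf, ph_icf = row$ph_icf,
                               cbf = row$cbf_ml_min_g)
  fill_healthy_defaults(tum, healthy)
}

#' Bundled blood-tumor-barrier fold-change estimates
#'
#' Paracellular pore-size and active-efflux-clearance fold changes of the BTB
#' over the control-brain BBB for each study case, with the estimation protocol
#' (simultaneous, or separate with the other parameter fixed to 1). The two
#' human patients form a single case (`case_id`).
#'
#' @return A data.frame.
#' @export
load_fold_change_table <- function() {
  utils::read.csv(extdata_path("fold_changes.csv"), stringsAsFactors = FALSE)
}

#' Bundled study summary table
#'
#' Per-study fraction unbound, control-brain type and steady-state unbound
#' partition coefficients (Kp_uu,ECF) in control brain and tumor, plus the
#' paracellular-permeability correction factor applied to the control model.
#'
#' @return A data.frame.
#' @export
load_study_table <- function() {
  utils::read.csv(extdata_path("studies.csv"), stringsAsFactors = FALSE)
}

#' Bundled empirical plasma PK models
#'
#' @return A data.frame of plasma model parameterizations (see
#'   [load_plasma_model()] to instantiate one).
#' @export
load_plasma_table <- function() {
  utils::read.csv(extdata_path("plasma_models.csv"), stringsAsFactors = FALSE)
}

#' Fetch one bundled plasma model
#'
#' Percent-scale variability columns are converted to standard deviations
#' (fractions); `fup_scale` carries the unbound correction for models fitted to
#' total drug.
#'
#' @param study Study identifier as in [load_plasma_table()].
#' @return A [plasma_pk_model] object.
#' @export
load_plasma_model <- function(study) {
  tab <- load_plasma_table()
  row <- tab[tab$study == study, ]
  if (nrow(row) != 1L) stop("unknown plasma study '", study, "'")
  num <- function(x) if (is.na(x)) NULL else x
  plasma_pk_model(structure = row$structure,
                  cl_cen = num(row$cl_cen), q_cen_per = num(row$q_cen_per),
                  v_cen = row$v_cen, v_per = num(row$v_per),
                  k_el = num(row$k_el), k_a = num(row$k_a), lag = num(row$lag),
                  omega_cl = row$omega_cl_pct / 100,
                  omega_v = row$omega_v_pct / 100,
                  sigma_prop = row$sigma_prop_pct / 100,
                  sigma_add = row$sigma_add,
                  fup_scale = row$fup_scale)
}
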