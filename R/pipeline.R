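#' Read / write observation tables
#'
#' Plain-CSV observation tables with pinned columns `subject_id`,
#' `compartment`, `time_min`, `interval_end_min`, `conc_ng_per_ml`,
#' `censored`. Unknown columns are rejected rather than silently ignored.
#' Lines starting with `#` (provenance headers) are skipped.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_concentration_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "compartment", "time_min", "interval_end_min",
            "conc_ng_per_ml", "censored")
  extra <- setdiff(names(tab), need)
  if (length(extra)) stop("unknown columns in ", path, ": ",
                          paste(extra, collapse = ", "))
  check_observation_table(tab)
  tab$censored <- as.logical(tab$censored)
  tab
}

#' @rdname read_concentration_table
#' @param tab Observation table to write.
#' @param digest Optional provenance digest written as a `#` header line.
#' @export
write_concentration_table <- function(tab, path, digest = NULL) {
  check_observation_table(tab)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(digest)) writeLines(paste0("# config_digest: ", digest), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read dose events from a YAML or JSON document
#'
#' The document is a list of events with keys `route`, `amount_ug`,
#' `start_min` and (for infusions) `duration_min`; unknown keys are rejected.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A list of [dose_event] objects.
#' @export
read_dose_events <- function(path) {
  doc <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  lapply(doc, function(d) {
    bad <- setdiff(names(d), c("route", "amount_ug", "start_min", "duration_min"))
    if (length(bad)) stop("unknown dose keys: ", paste(bad, collapse = ", "))
    dose_event(route = d$route, amount = d$amount_ug,
               start = if (is.null(d$start_min)) 0 else d$start_min,
               duration = d$duration_min)
  })
}

#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Every stochastic stage is
#' governed by the mandatory `seed`; unknown keys are rejected before any
#' computation.
#'
#' @param drug Bundled drug name (see [load_drug_table()]).
#' @param species `"rat"` or `"human"`.
#' @param tumor_model Bundled tumor model name (see [load_tumor_table()]).
#' @param plasma_study Bundled plasma study id (see [load_plasma_table()]).
#' @param dose List with `route`, `amount_ug`, `start_min`, `duration_min`.
#' @param kpuu_control Measured control-brain Kp_uu,ECF.
#' @param true_ppa_correction,true_f_pore,true_f_efflux Generating parameters
#'   of the synthetic study.
#' @param schedule Sampling schedule (bin edges, min).
#' @param n_subjects Subjects in the synthetic study.
#' @param lloq Lower limit of quantification (ng/mL).
#' @param sampling_mode `"interval_mean"` or `"point"`.
#' @param stages Character subset of `c("generate", "ppa", "handshake",
#'   "vpc", "accuracy")`, executed in this order.
#' @param n_sim VPC replicate count.
#' @param seed Mandatory integer seed.
#' @param out_dir Output directory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(drug, species, tumor_model, plasma_study, dose,
                       kpuu_control, true_ppa_correction = 1,
                       true_f_pore = 1, true_f_efflux = 1,
                       schedule = seq(0, 360, by = 20), n_subjects = 6,
                       lloq = 0, sampling_mode = "interval_mean",
                       stages = c("generate", "ppa", "handshake", "vpc",
                                  "accuracy"),
                       n_sim = 200, seed, out_dir) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  known <- c("generate", "ppa", "handshake", "vpc", "accuracy")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  cfg <- list(drug = drug, species = species, tumor_model = tumor_model,
              plasma_study = plasma_study, dose = dose,
              kpuu_control = kpuu_control,
              true_ppa_correction = true_ppa_correction,
              true_f_pore = true_f_pore, true_f_efflux = true_f_efflux,
              schedule = schedule, n_subjects = n_subjects, lloq = lloq,
              sampling_mode = sampling_mode, stages = stages, n_sim = n_sim,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()];
#'   unknown keys are rejected.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "")
  bad <- setdiff(names(doc), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, doc)
}

config_digest <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- unclass(cfg)
  plain$out_dir <- NULL  # digest is location-independent
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full two-stage analysis pipeline
#'
#' Executes the requested stages in order on a synthetic study: generate the
#' study, estimate the paracellular correction from the control arm, estimate
#' the BTB fold changes from the tumor arm, run a visual predictive check of
#' the fitted model and compute the relative-accuracy statistic. Each stage
#' reads the previous stage's outputs; all artifacts (CSV/JSON) carry the
#' config digest, and a machine-readable `summary.json` collects estimates
#' and diagnostics.
#'
#' @param cfg A [run_config] (or path to a YAML config).
#' @return Invisibly, the summary list; artifacts are written to
#'   `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  digest <- config_digest(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed (config digest ", digest,
           ", seed ", cfg$seed, "): ", conditionMessage(e), call. = FALSE))
  }
  drug <- load_drug(cfg$drug)
  phys <- default_physiology(cfg$species)
  tum <- load_tumor_model(cfg$tumor_model, phys)
  pm <- load_plasma_model(cfg$plasma_study)
  doses <- list(dose_event(route = cfg$dose$route, amount = cfg$dose$amount_ug,
                           start = if (is.null(cfg$dose$start_min)) 0 else cfg$dose$start_min,
                           duration = cfg$dose$duration_min))
  design <- study_design(drug, phys, tum, pm, doses, schedule = cfg$schedule,
                         n_subjects = cfg$n_subjects,
                         kpuu_control = cfg$kpuu_control,
                         true_ppa_correction = cfg$true_ppa_correction,
                         true_folds = fold_changes(cfg$true_f_pore,
                                                   cfg$true_f_efflux),
                         lloq = cfg$lloq, sampling_mode = cfg$sampling_mode,
                         seed = cfg$seed)
  summary <- list(config_digest = digest, seed = cfg$seed,
                  stages = cfg$stages)
  study <- NULL
  base <- cns_model_spec(drug, phys, pm, ppa_correction = 1,
                         kpuu_ecf_target = cfg$kpuu_control)
  tspec <- NULL

  if ("generate" %in% cfg$stages) {
    study <- stage("generate", generate_study(design))
    write_concentration_table(study$observations,
                              file.path(cfg$out_dir, "study.csv"), digest)
  } else {
    study <- stage("load", list(observations = read_concentration_table(
      file.path(cfg$out_dir, "study.csv"))))
  }
  if ("ppa" %in% cfg$stages) {
    fit1 <- stage("ppa", estimate_ppa_correction(study$observations, base,
                                                 doses, lloq = cfg$lloq))
    base$ppa_correction <- fit1$ppa_correction
    summary$ppa_correction <- fit1$ppa_correction
    jsonlite::write_json(list(config_digest = digest,
                              ppa_correction = fit1$ppa_correction,
                              objective = fit1$objective_value),
                         file.path(cfg$out_dir, "ppa.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("handshake" %in% cfg$stages) {
    tspec <- tumor_model_spec(base, tum, fold_changes())
    fit2 <- stage("handshake",
                  estimate_fold_changes(study$observations, tspec, doses,
                                        lloq = cfg$lloq, seed = cfg$seed))
    tspec$folds <- fold_changes(fit2$f_pore, fit2$f_efflux)
    summary$f_pore <- fit2$f_pore
    summary$f_efflux <- fit2$f_efflux
    summary$ridge_flag <- fit2$ridge_flag
    summary$start_dispersion <- fit2$start_dispersion
    jsonlite::write_json(list(config_digest = digest, f_pore = fit2$f_pore,
                              f_efflux = fit2$f_efflux,
                              ridge_flag = fit2$ridge_flag,
                              start_dispersion = fit2$start_dispersion),
                         file.path(cfg$out_dir, "handshake.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("vpc" %in% cfg$stages || "accuracy" %in% cfg$stages) {
    if (is.null(tspec))
      tspec <- tumor_model_spec(base, tum,
                                fold_changes(cfg$true_f_pore, cfg$true_f_efflux))
    vres <- stage("vpc", vpc(tspec, doses, study$observations,
                             n_sim = cfg$n_sim, seed = cfg$seed + 1L))
    if ("vpc" %in% cfg$stages) {
      con <- file(file.path(cfg$out_dir, "vpc.csv"), "w")
      writeLines(paste0("# config_digest: ", digest), con)
      utils::write.csv(as.data.frame(vres), con, row.names = FALSE)
      close(con)
    }
    if ("accuracy" %in% cfg$stages) {
      acc <- stage("accuracy",
                   relative_accuracy(study$observations, vres$median))
      summary$ra_drug <- acc$ra_drug
      summary$twofold_fraction <- acc$twofold_fraction
      jsonlite::write_json(list(config_digest = digest, ra_drug = acc$ra_drug,
                                twofold_fraction = acc$twofold_fraction,
                                m_total = acc$m_total),
                           file.path(cfg$out_dir, "accuracy.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
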