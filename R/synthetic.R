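#' Synthetic microdialysis study design
#'
#' Describes a study with plasma, control-brain ECF and tumor ECF arms the way
#' microdialysis experiments produce them: sparse interval-averaged unbound
#' concentrations per subject, exponential inter-individual variability on the
#' plasma parameters, proportional(/additive) residual error and censoring at
#' the lower limit of quantification. The default schedule emulates 20-min
#' dialysate bins over 0-360 min.
#'
#' @param drug A [drug_properties] object.
#' @param physiology A [cns_physiology] object.
#' @param tumor A [tumor_pathophysiology] object.
#' @param plasma A [plasma_pk_model] (carries the IIV and RUV magnitudes).
#' @param doses Dose events shared by all subjects.
#' @param schedule Increasing times (min): bin edges for `interval_mean`
#'   sampling, sampling times for `point` sampling.
#' @param n_subjects Number of subjects (>= 1).
#' @param kpuu_control Measured control-brain Kp_uu,ECF used to set the
#'   asymmetry factors of the true model.
#' @param true_ppa_correction Generating paracellular correction factor.
#' @param true_folds Generating [fold_changes].
#' @param lloq Lower limit of quantification (ng/mL).
#' @param sampling_mode `"interval_mean"` (dialysate bins) or `"point"`.
#' @param seed Mandatory integer seed.
#' @return An object of class `study_design`.
#' @export
study_design <- function(drug, physiology, tumor, plasma, doses,
                         schedule = seq(0, 360, by = 20), n_subjects = 6,
                         kpuu_control, true_ppa_correction = 1,
                         true_folds = fold_changes(), lloq = 0,
                         sampling_mode = c("interval_mean", "point"), seed) {
  sampling_mode <- match.arg(sampling_mode)
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  if (n_subjects < 1) stop("'n_subjects' must be >= 1")
  if (length(schedule) < 2 || is.unsorted(schedule, strictly = TRUE))
    stop("'schedule' must be strictly increasing with >= 2 times")
  structure(list(drug = drug, physiology = physiology, tumor = tumor,
                 plasma = plasma, doses = doses, schedule = schedule,
                 n_subjects = n_subjects, kpuu_control = kpuu_control,
                 true_ppa_correction = true_ppa_correction,
                 true_folds = true_folds, lloq = lloq,
                 sampling_mode = sampling_mode, seed = as.integer(seed)),
            class = "study_design")
}

# True (generating) model specs implied by a design.
design_specs <- function(design) {
  base <- cns_model_spec(design$drug, design$physiology, design$plasma,
                         ppa_correction = design$true_ppa_correction,
                         kpuu_ecf_target = design$kpuu_control)
  list(base = base,
       tumor = tumor_model_spec(base, design$tumor, design$true_folds))
}

#' Generate a synthetic microdialysis study
#'
#' Per subject: samples plasma IIV deviations, simulates the true control and
#' tumor models, samples the schedule (point values, or trapezoid
#' time-averages over bins for interval sampling), applies residual error and
#' censors below the LLOQ (censored rows carry the LLOQ as value). Fully
#' reproducible from the design seed.
#'
#' @param design A [study_design].
#' @return A list of class `study_dataset`: `observations` (data.frame),
#'   `design`, and `truth` (generating parameters, incl. per-subject etas).
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  specs <- design_specs(design)
  pm <- design$plasma
  sch <- design$schedule
  interval <- design$sampling_mode == "interval_mean"
  if (interval) {
    tmpl <- data.frame(time_min = utils::head(sch, -1),
                       interval_end_min = utils::tail(sch, -1))
  } else {
    tmpl <- data.frame(time_min = sch, interval_end_min = NA_real_)
  }
  arms <- c("plasma", "control_ecf", "tumor_ecf")
  etas <- data.frame(subject_id = character(), eta_cl = numeric(),
                     eta_v = numeric())
  obs_list <- list()
  for (s in seq_len(design$n_subjects)) {
    sid <- sprintf("S%02d", s)
    eta <- c(cl = if (pm$omega_cl > 0) stats::rnorm(1, 0, pm$omega_cl) else 0,
             v = if (pm$omega_v > 0) stats::rnorm(1, 0, pm$omega_v) else 0)
    etas <- rbind(etas, data.frame(subject_id = sid, eta_cl = eta[["cl"]],
                                   eta_v = eta[["v"]]))
    skel <- do.call(rbind, lapply(arms, function(a)
      cbind(subject_id = sid, compartment = a, tmpl,
            conc_ng_per_ml = NA_real_, censored = FALSE)))
    pred <- predict_observations(specs$tumor, design$doses, skel, eta = eta)
    noisy <- apply_ruv(data.frame(conc_ng_per_ml = pred), pm)
    skel$conc_ng_per_ml <- noisy$conc_ng_per_ml
    skel$censored <- skel$conc_ng_per_ml < design$lloq
    skel$conc_ng_per_ml[skel$censored] <- design$lloq
    obs_list[[s]] <- skel
  }
  out <- list(observations = do.call(rbind, obs_list), design = design,
              truth = list(ppa_correction = design$true_ppa_correction,
                           f_pore = design$true_folds$f_pore,
                           f_efflux = design$true_folds$f_efflux,
                           kpuu_control = design$kpuu_control,
                           etas = etas))
  class(out) <- "study_dataset"
  out
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset> ", x$design$n_subjects, " subject(s), ",
      nrow(x$observations), " observations (",
      sum(x$observations$censored), " censored)\n", sep = "")
  invisible(x)
}

#' Parameter-recovery experiment for the handshake workflow
#'
#' Loops seeded replicates of generate-then-estimate: each replicate draws a
#' fresh synthetic study from the design, estimates the paracellular
#' correction from the control arm, then the BTB fold changes from the tumor
#' arm (with the estimated correction in place), and records truth, estimates
#' and relative errors. Per-replicate estimation failures are recorded, not
#' propagated.
#'
#' @param design A [study_design] (its seed is replaced per replicate).
#' @param n_replicates Number of replicates (0 gives an empty table).
#' @param seed Base seed; replicate r uses `seed + 1000 * r`.
#' @param estimator Options list: `ppa_starts` (stage-1 start grid),
#'   `estimate_ppa` (set `FALSE` to keep the correction at the design's true
#'   value, the protocol used for drugs whose control ECF profile is
#'   insensitive to the paracellular route), `f_pore_grid`, `f_efflux_grid`
#'   (stage-2 start grids), `rtol`, `lloq`.
#' @return A data.frame with one row per replicate: truth, estimates,
#'   relative errors, ridge flag and error messages.
#' @export
recovery_experiment <- function(design, n_replicates, seed = 1,
                                estimator = list()) {
  est_defaults <- list(
    f_pore_grid = 10^seq(-0.5, 2, length.out = 3),
    f_efflux_grid = c(-1, 0.5, 3),
    ppa_starts = 10^seq(0, 2, length.out = 3),
    estimate_ppa = TRUE,
    rtol = 1e-6, lloq = design$lloq)
  est <- utils::modifyList(est_defaults, estimator)
  rows <- vector("list", n_replicates)
  if (n_replicates == 0)
    return(data.frame(replicate = integer(), true_ppa = numeric(),
                      est_ppa = numeric(), true_f_pore = numeric(),
                      est_f_pore = numeric(), true_f_efflux = numeric(),
                      est_f_efflux = numeric(), rel_err_ppa = numeric(),
                      rel_err_f_pore = numeric(), rel_err_f_efflux = numeric(),
                      ridge_flag = logical(), error = character()))
  for (r in seq_len(n_replicates)) {
    d <- design
    d$seed <- as.integer(seed + 1000 * r)
    row <- data.frame(replicate = r, true_ppa = design$true_ppa_correction,
                      est_ppa = NA_real_,
                      true_f_pore = design$true_folds$f_pore,
                      est_f_pore = NA_real_,
                      true_f_efflux = design$true_folds$f_efflux,
                      est_f_efflux = NA_real_, rel_err_ppa = NA_real_,
                      rel_err_f_pore = NA_real_, rel_err_f_efflux = NA_real_,
                      ridge_flag = NA, error = "")
    res <- tryCatch({
      ds <- generate_study(d)
      specs <- design_specs(d)
      base <- specs$base
      if (est$estimate_ppa) {
        base$ppa_correction <- 1  # unknown to the estimator
        fit1 <- estimate_ppa_correction(ds$observations, base, d$doses,
                                        lloq = est$lloq,
                                        starts = est$ppa_starts,
                                        rtol = est$rtol)
        ppa_hat <- fit1$ppa_correction
      } else {
        ppa_hat <- base$ppa_correction
      }
      base$ppa_correction <- ppa_hat
      tspec <- tumor_model_spec(base, d$tumor, fold_changes())
      fit2 <- estimate_fold_changes(ds$observations, tspec, d$doses,
                                    lloq = est$lloq,
                                    f_pore_grid = est$f_pore_grid,
                                    f_efflux_grid = est$f_efflux_grid,
                                    seed = d$seed, rtol = est$rtol)
      list(ppa = ppa_hat, fp = fit2$f_pore, fe = fit2$f_efflux,
           ridge = fit2$ridge_flag)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$est_ppa <- res$ppa
      row$est_f_pore <- res$fp
      row$est_f_efflux <- res$fe
      row$ridge_flag <- res$ridge
      row$rel_err_ppa <- (res$ppa - row$true_ppa) / row$true_ppa
      row$rel_err_f_pore <- (res$fp - row$true_f_pore) / row$true_f_pore
      row$rel_err_f_efflux <- (res$fe - row$true_f_efflux) / row$true_f_efflux
    }
    rows[[r]] <- row
  }
  do.call(rbind, rows)
}
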