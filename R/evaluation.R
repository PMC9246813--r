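#' Visual predictive check
#'
#' Simulates the model `n_sim` times with inter-individual variability (normal
#' deviations on the log of plasma clearance and central volume) and residual
#' error sampled per observation, and summarizes the replicates as the
#' pointwise median and 95% prediction interval at the observation schedule.
#' Percentiles use linear interpolation between order statistics (R quantile
#' type 7).
#'
#' @param spec A [plasma_pk_model], [cns_model_spec] or [tumor_model_spec].
#' @param doses Dose events.
#' @param data Observation table defining the schedule (compartments, times,
#'   intervals); see [predict_observations()].
#' @param n_sim Number of stochastic replicates (default 200, >= 2).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A data.frame of class `vpc_result` aligned with `data` rows:
#'   `compartment`, `time_min`, `interval_end_min`, `median`, `lower_2_5`,
#'   `upper_97_5`; `attr(, "n_sim")` records the replicate count.
#' @export
vpc <- function(spec, doses, data, n_sim = 200, seed = 1) {
  if (n_sim < 2) stop("'n_sim' must be at least 2")
  check_observation_table(data)
  pm <- if (inherits(spec, "plasma_pk_model")) spec else spec_plasma(spec)
  plasma_only <- inherits(spec, "plasma_pk_model")
  set.seed(seed)
  sims <- matrix(NA_real_, nrow(data), n_sim)
  for (k in seq_len(n_sim)) {
    eta <- c(cl = if (pm$omega_cl > 0) stats::rnorm(1, 0, pm$omega_cl) else 0,
             v = if (pm$omega_v > 0) stats::rnorm(1, 0, pm$omega_v) else 0)
    if (plasma_only) {
      ts <- sort(unique(data$time_min))
      pred <- simulate_plasma(spec, doses, ts, eta = eta)$conc_ng_per_ml[
        match(data$time_min, ts)]
    } else {
      pred <- predict_observations(spec, doses, data, eta = eta)
    }
    sims[, k] <- apply_ruv(data.frame(conc_ng_per_ml = pred), pm)$conc_ng_per_ml
  }
  qs <- t(apply(sims, 1, stats::quantile, probs = c(0.5, 0.025, 0.975),
                type = 7, names = FALSE))
  out <- data.frame(compartment = data$compartment, time_min = data$time_min,
                    interval_end_min = data$interval_end_min,
                    median = qs[, 1], lower_2_5 = qs[, 2], upper_97_5 = qs[, 3])
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  class(out) <- c("vpc_result", "data.frame")
  out
}

#' Relative accuracy of model predictions
#'
#' The relative accuracy error is the mean, over all observations of all
#' individuals, of log10 of the matched median prediction over the
#' observation:
#' `RA = (1/M) * sum_i sum_j log10(MedP_ij / Obs_ij)`, with `M` the total
#' observation count. Zero means unbiased prediction on the log scale;
#' `log10(2)` corresponds to a uniform twofold over-prediction. Also reports
#' the fraction of observations predicted within twofold.
#'
#' @param obs Observation table (needs `subject_id` and `conc_ng_per_ml`;
#'   censored rows and non-positive observations are excluded with a warning
#'   count).
#' @param median_pred Matched median predictions, one per observation row.
#' @return A list of class `accuracy_report`: `ra_drug`, `m_per_individual`,
#'   `m_total`, `n_individuals`, `twofold_fraction`, `n_excluded`.
#' @export
relative_accuracy <- function(obs, median_pred) {
  if (length(median_pred) != nrow(obs))
    stop("'median_pred' must match the observation rows")
  cens <- if ("censored" %in% names(obs)) obs$censored else rep(FALSE, nrow(obs))
  use <- !cens & obs$conc_ng_per_ml > 0 & is.finite(median_pred) & median_pred > 0
  n_excl <- sum(!use)
  if (n_excl > 0)
    warning(n_excl, " observation(s) excluded (censored or non-positive)")
  if (!any(use)) stop("no usable observations")
  lr <- log10(median_pred[use] / obs$conc_ng_per_ml[use])
  subj <- factor(obs$subject_id[use])
  m_i <- as.integer(table(subj))
  out <- list(ra_drug = mean(lr),
              m_per_individual = stats::setNames(m_i, levels(subj)),
              m_total = length(lr),
              n_individuals = nlevels(subj),
              twofold_fraction = mean(abs(lr) <= log10(2)),
              n_excluded = n_excl)
  class(out) <- "accuracy_report"
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> RA %.5f (log10), %.1f%% within twofold (M = %d, N = %d)\n",
              x$ra_drug, 100 * x$twofold_fraction, x$m_total, x$n_individuals))
  invisible(x)
}

# Resolve a scan parameter inside a spec; returns a modifier function.
scan_modifier <- function(spec, parameter_name) {
  phys_fields <- if (inherits(spec, "tumor_model_spec"))
    names(spec$base$physiology) else names(spec$physiology)
  tumor_fields <- if (inherits(spec, "tumor_model_spec")) names(spec$tumor) else character()
  valid <- c("ppa_correction", phys_fields,
             if (length(tumor_fields)) paste0("tumor.", tumor_fields),
             "f_pore", "f_efflux")
  if (!parameter_name %in% valid)
    stop("unknown parameter '", parameter_name, "'; valid names: ",
         paste(valid, collapse = ", "))
  function(spec, value) {
    if (parameter_name == "ppa_correction") {
      if (inherits(spec, "tumor_model_spec")) spec$base$ppa_correction <- value
      else spec$ppa_correction <- value
    } else if (parameter_name %in% c("f_pore", "f_efflux")) {
      if (!inherits(spec, "tumor_model_spec"))
        stop("fold changes only exist in tumor specs")
      spec$folds[[parameter_name]] <- value
    } else if (startsWith(parameter_name, "tumor.")) {
      spec$tumor[[sub("^tumor\\.", "", parameter_name)]] <- value
    } else if (inherits(spec, "tumor_model_spec")) {
      spec$base$physiology[[parameter_name]] <- value
    } else {
      spec$physiology[[parameter_name]] <- value
    }
    spec
  }
}

#' One-at-a-time sensitivity scan
#'
#' Re-simulates the model over a grid of values of a single named parameter,
#' everything else frozen, and reports ECF exposure metrics per grid point:
#' maximum concentration, its time, and the trapezoidal area under the curve
#' on the simulation grid.
#'
#' @param spec A [cns_model_spec] or [tumor_model_spec].
#' @param parameter_name Name of the parameter to scan: `"ppa_correction"`,
#'   any physiology field, `tumor.<field>` for tumor fields, or `f_pore` /
#'   `f_efflux`.
#' @param grid Numeric vector of parameter values.
#' @param doses Dose events.
#' @param times Simulation output grid (min).
#' @param compartment Simulated compartment to summarize (default
#'   `"brain_ecf"`).
#' @return A data.frame: `value`, `cmax`, `tmax`, `auc`.
#' @export
sensitivity_scan <- function(spec, parameter_name, grid, doses, times,
                             compartment = "brain_ecf") {
  modify <- scan_modifier(spec, parameter_name)
  rows <- lapply(grid, function(v) {
    sim <- simulate_cns(modify(spec, v), doses, times)
    cc <- sim$conc_ng_per_ml[sim$compartment == compartment]
    tt <- sim$time_min[sim$compartment == compartment]
    data.frame(value = v, cmax = max(cc), tmax = tt[which.max(cc)],
               auc = sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2))
  })
  do.call(rbind, rows)
}
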