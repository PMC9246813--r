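#' Empirical plasma pharmacokinetic model
#'
#' One- or two-compartment linear plasma model used as the forcing function of
#' the CNS model, with optional first-order absorption and lag time,
#' exponential inter-individual variability (IIV) on clearance and central
#' volume, and proportional / combined residual error.
#'
#' @param structure `"one_compartment"` or `"two_compartment"`.
#' @param cl_cen Central clearance (mL/min). Exactly one of `cl_cen`, `k_el`
#'   must drive elimination.
#' @param q_cen_per Inter-compartmental clearance (mL/min, 2-cmt only).
#' @param v_cen Central volume (mL).
#' @param v_per Peripheral volume (mL, 2-cmt only).
#' @param k_el Elimination rate constant (1/min), alternative to `cl_cen`.
#' @param k_a First-order absorption rate constant (1/min, optional).
#' @param lag Absorption lag time (min); requires `k_a`.
#' @param omega_cl,omega_v IIV standard deviations on the log scale for
#'   clearance (or `k_el`) and central volume.
#' @param sigma_prop Proportional residual error SD (fraction).
#' @param sigma_add Additive residual error SD (ng/mL).
#' @param fup_scale Multiplier converting the model prediction to unbound
#'   concentration (1 when the model already describes unbound drug; the
#'   plasma fraction unbound when it describes total drug).
#' @return An object of class `plasma_pk_model`.
#' @export
plasma_pk_model <- function(structure = c("one_compartment", "two_compartment"),
                            cl_cen = NULL, q_cen_per = NULL, v_cen,
                            v_per = NULL, k_el = NULL, k_a = NULL, lag = NULL,
                            omega_cl = 0, omega_v = 0,
                            sigma_prop = 0, sigma_add = 0, fup_scale = 1) {
  structure <- match.arg(structure)
  if (is.null(cl_cen) == is.null(k_el))
    stop("exactly one of 'cl_cen' and 'k_el' must be given")
  if (!is.null(lag) && is.null(k_a)) stop("'lag' requires 'k_a'")
  if (structure == "two_compartment" && (is.null(q_cen_per) || is.null(v_per)))
    stop("a two-compartment model requires 'q_cen_per' and 'v_per'")
  num_ok <- function(x) is.null(x) || (is.numeric(x) && is.finite(x) && x >= 0)
  for (nm in c("cl_cen", "q_cen_per", "v_cen", "v_per", "k_el", "k_a", "lag",
               "omega_cl", "omega_v", "sigma_prop", "sigma_add"))
    if (!num_ok(get(nm))) stop("'", nm, "' must be a non-negative number")
  if (v_cen <= 0) stop("'v_cen' must be positive")
  out <- list(structure = structure, cl_cen = cl_cen, q_cen_per = q_cen_per,
              v_cen = v_cen, v_per = v_per, k_el = k_el, k_a = k_a, lag = lag,
              omega_cl = omega_cl, omega_v = omega_v,
              sigma_prop = sigma_prop, sigma_add = sigma_add,
              fup_scale = fup_scale)
  class(out) <- "plasma_pk_model"
  out
}

#' @export
print.plasma_pk_model <- function(x, ...) {
  el <- if (!is.null(x$cl_cen)) paste0("CL ", x$cl_cen, " mL/min")
        else paste0("k_el ", x$k_el, " 1/min")
  cat("<plasma_pk_model> ", x$structure, ": ", el, ", V_cen ", x$v_cen, " mL",
      if (!is.null(x$q_cen_per)) paste0(", Q ", x$q_cen_per, ", V_per ", x$v_per),
      if (!is.null(x$k_a)) paste0(", ka ", x$k_a,
                                  if (!is.null(x$lag)) paste0(", lag ", x$lag)),
      "\n", sep = "")
  invisible(x)
}

#' Dosing event
#'
#' @param route `"iv_bolus"`, `"iv_infusion"` or `"depot"`.
#' @param amount Dose amount (ug), positive.
#' @param start Start time (min).
#' @param duration Infusion duration (min), required for infusions.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(route = c("iv_bolus", "iv_infusion", "depot"),
                       amount, start = 0, duration = NULL) {
  route <- match.arg(route)
  if (!is.numeric(amount) || amount <= 0) stop("'amount' must be positive")
  if (route == "iv_infusion" && (is.null(duration) || duration <= 0))
    stop("infusions require a positive 'duration'")
  structure(list(route = route, amount = amount, start = start,
                 duration = duration), class = "dose_event")
}

# Individual parameters after applying exponential IIV deviations.
individual_plasma <- function(model, eta = NULL) {
  if (is.null(eta)) return(model)
  e_cl <- if ("cl" %in% names(eta)) eta[["cl"]] else 0
  e_v <- if ("v" %in% names(eta)) eta[["v"]] else 0
  if (!is.null(model$cl_cen)) model$cl_cen <- model$cl_cen * exp(e_cl)
  if (!is.null(model$k_el)) model$k_el <- model$k_el * exp(e_cl)
  model$v_cen <- model$v_cen * exp(e_v)
  model
}

# Linear rate matrix of the plasma system (amount units).
# States: [depot,] central [, peripheral]; returns indices of dose targets.
plasma_matrix <- function(model) {
  has_dep <- !is.null(model$k_a)
  two <- model$structure == "two_compartment"
  n <- 1L + has_dep + two
  A <- matrix(0, n, n)
  cen <- 1L + has_dep
  k10 <- if (!is.null(model$cl_cen)) model$cl_cen / model$v_cen else model$k_el
  A[cen, cen] <- A[cen, cen] - k10
  if (two) {
    per <- cen + 1L
    k12 <- model$q_cen_per / model$v_cen
    k21 <- model$q_cen_per / model$v_per
    A[cen, cen] <- A[cen, cen] - k12
    A[per, cen] <- k12
    A[cen, per] <- k21
    A[per, per] <- -k21
  }
  if (has_dep) {
    ka <- model$k_a
    # guard against exact eigenvalue degeneracy of ka with a disposition rate
    ev <- eigen(A[-1, -1, drop = FALSE], only.values = TRUE)$values
    if (any(abs(Re(ev) + ka) < 1e-10)) ka <- ka * (1 + 1e-8)
    A[1, 1] <- -ka
    A[cen, 1] <- ka
  }
  list(A = A, central = cen, depot = if (has_dep) 1L else NULL, n = n)
}

# Analytic propagation of dx/dt = A x via eigen-decomposition.
# Returns functions evaluating the bolus and constant-infusion responses.
eigen_solution <- function(A) {
  eg <- eigen(A)
  P <- eg$vectors
  Pinv <- solve(P)
  lam <- eg$values
  list(
    # e^{A tau} v at tau >= 0 (columns = tau values)
    bolus = function(v, tau) {
      co <- as.vector(Pinv %*% v)
      Re(P %*% (exp(outer(lam, tau)) * co))
    },
    # int_0^tau e^{A s} ds v = A^{-1}(e^{A tau} - I) v
    infusion = function(v, tau) {
      co <- as.vector(Pinv %*% v)
      lt <- outer(lam, tau)
      phi <- ifelse(abs(lt) < 1e-12, rep(tau, each = length(lam)),
                    (exp(lt) - 1)) / ifelse(abs(lam) < 1e-14, 1, lam)
      Re(P %*% (phi * co))
    })
}

# Superpose dose responses of a linear system dx/dt = A x with inputs into
# 'central' (iv routes) or 'depot' (first-order absorption, shifted by 'lag').
# Returns the state matrix (n x length(times)).
propagate_doses <- function(sol, n, doses, central, depot, lag, times) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  x <- matrix(0, n, length(times))
  for (d in doses) {
    if (d$route == "depot") {
      if (is.null(depot)) stop("depot dose requires a model with 'k_a'")
      t0 <- d$start + if (is.null(lag)) 0 else lag
      tau <- times - t0
      act <- tau > 0
      if (any(act)) {
        v <- numeric(n); v[depot] <- d$amount
        x[, act] <- x[, act] + sol$bolus(v, tau[act])
      }
    } else if (d$route == "iv_bolus") {
      tau <- times - d$start
      act <- tau > 0
      if (any(act)) {
        v <- numeric(n); v[central] <- d$amount
        x[, act] <- x[, act] + sol$bolus(v, tau[act])
      }
    } else {  # iv_infusion
      rate <- d$amount / d$duration
      v <- numeric(n); v[central] <- rate
      tau <- times - d$start
      during <- tau > 0 & tau <= d$duration
      after <- tau > d$duration
      if (any(during))
        x[, during] <- x[, during] + sol$infusion(v, tau[during])
      if (any(after)) {
        end_state <- as.vector(sol$infusion(v, d$duration))
        x[, after] <- x[, after] + sol$bolus(end_state, tau[after] - d$duration)
      }
    }
  }
  x
}

# State trajectory (amount, ug) of the plasma model at 'times' (min).
# 'cache' may carry a precomputed plasma_matrix()/eigen_solution() pair.
plasma_states <- function(model, doses, times, cache = NULL) {
  sys <- if (is.null(cache)) plasma_matrix(model) else cache$sys
  sol <- if (is.null(cache)) eigen_solution(sys$A) else cache$sol
  x <- propagate_doses(sol, sys$n, doses, sys$central, sys$depot, model$lag,
                       times)
  list(x = x, central = sys$central)
}

#' Simulate a plasma concentration-time profile
#'
#' Closed-form (eigen-decomposition) solution of the linear plasma system with
#' superposition over dosing events. Concentrations are on the scale the model
#' was parameterized on (total drug for models of total concentrations);
#' multiply by `fup_scale` for the unbound forcing.
#'
#' @param model A [plasma_pk_model].
#' @param doses A [dose_event] or list of them.
#' @param times Sorted, non-negative sampling times (min).
#' @param eta Optional named individual deviations `c(cl = , v = )` applied as
#'   `CL_i = CL * exp(eta_cl)`, `V_i = V * exp(eta_v)`.
#' @return A data.frame with `time_min` and `conc_ng_per_ml`.
#' @export
simulate_plasma <- function(model, doses, times, eta = NULL) {
  stopifnot(inherits(model, "plasma_pk_model"))
  if (is.unsorted(times)) stop("'times' must be sorted")
  if (any(times < 0)) stop("'times' must be non-negative")
  ind <- individual_plasma(model, eta)
  st <- plasma_states(ind, doses, times)
  conc <- 1000 * st$x[st$central, ] / ind$v_cen  # ug/mL -> ng/mL
  data.frame(time_min = times, conc_ng_per_ml = pmax(conc, 0))
}

#' Plasma concentration as a function of time
#'
#' Returns a vectorized function `f(t)` giving the model-scale plasma
#' concentration (ng/mL); used internally as the CNS forcing function.
#'
#' @inheritParams simulate_plasma
#' @return A function of time.
#' @export
plasma_conc_fn <- function(model, doses, eta = NULL) {
  ind <- individual_plasma(model, eta)
  sys <- plasma_matrix(ind)
  cache <- list(sys = sys, sol = eigen_solution(sys$A))
  function(t) {
    st <- plasma_states(ind, doses, t, cache = cache)
    pmax(1000 * st$x[st$central, ] / ind$v_cen, 0)
  }
}

#' Apply residual unexplained variability to predictions
#'
#' Observation noise `obs = pred * (1 + eps_prop) + eps_add` with independent
#' normal deviates; negative results are floored at 0 and flagged.
#'
#' @param pred A data.frame with a `conc_ng_per_ml` column.
#' @param model A [plasma_pk_model] carrying `sigma_prop`, `sigma_add`.
#' @param seed Optional integer seed for reproducible noise.
#' @return `pred` with perturbed concentrations and a logical `floored` column.
#' @export
apply_ruv <- function(pred, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pred)
  e_p <- if (model$sigma_prop > 0) stats::rnorm(n, 0, model$sigma_prop) else numeric(n)
  e_a <- if (model$sigma_add > 0) stats::rnorm(n, 0, model$sigma_add) else numeric(n)
  obs <- pred$conc_ng_per_ml * (1 + e_p) + e_a
  pred$floored <- obs < 0
  pred$conc_ng_per_ml <- pmax(obs, 0)
  pred
}
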