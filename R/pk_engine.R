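# pk_engine: exact linear disposition kinetics ----------------------------
#
# Concentrations are computed by piecewise-analytic propagation: within any
# span of time where the individual parameters and the infusion rate are
# constant, the one- or two-compartment linear system has a closed-form
# solution (a 2x2 matrix exponential for two compartments), and the
# compartment amounts are carried exactly across segment boundaries. This is
# exact to machine precision for arbitrary infusion schedules and
# piecewise-constant parameters; no ODE solver is involved.

#' Individual structural parameters from typical values, covariates and
#' random effects
#'
#' Each structural parameter is the typical value multiplied by the product
#' of its covariate-effect multipliers and `exp(eta)`; clearance is further
#' multiplied by `exp(kappa)` when an occasion effect applies.
#'
#' @param model A [poppk_model()].
#' @param covariates Named list of covariate values at the evaluation time.
#'   Binary covariates may be logical or 0/1.
#' @param eta Named numeric vector of inter-individual effects (log scale);
#'   names must match structural parameters. Missing entries are 0.
#' @param kappa Occasion effect on `CL` (log scale).
#' @param time Evaluation time in hours (used by time-switch effects).
#' @return Named list `CL`, `Vc` (and `Q`, `Vp` for 2-compartment models),
#'   clearances in L/day, volumes in L.
#' @export
individual_parameters <- function(model, covariates = list(), eta = NULL,
                                  kappa = 0, time = 0) {
  stopifnot(inherits(model, "poppk_model"))
  pars <- lapply(model$typical, identity)
  for (eff in model$covariate_effects) {
    mult <- covariate_multiplier(eff, covariates, time)
    pars[[eff$target]] <- pars[[eff$target]] * mult
  }
  if (!is.null(eta) && length(eta)) {
    if (is.null(names(eta))) stop("eta must be named", call. = FALSE)
    for (nm in names(eta)) {
      if (!nm %in% names(pars)) {
        stop("eta names a parameter absent from the model: ", nm, call. = FALSE)
      }
      pars[[nm]] <- pars[[nm]] * exp(eta[[nm]])
    }
  }
  pars$CL <- pars$CL * exp(kappa)
  pars
}

covariate_multiplier <- function(eff, covariates, time) {
  if (eff$form == "piecewise_time_multiplier") {
    return(if (time >= (eff$reference %||% 0)) eff$coefficient else 1)
  }
  val <- covariates[[eff$covariate]]
  if (is.null(val) || (length(val) == 1 && is.na(val))) {
    stop("covariate '", eff$covariate, "' required by model effect on ",
         eff$target, " is missing", call. = FALSE)
  }
  switch(eff$form,
    power = (val / eff$reference)^eff$coefficient,
    proportional = 1 + eff$coefficient * (val - (eff$reference %||% 0)),
    exponential = exp(eff$coefficient * (val - (eff$reference %||% 0))),
    binary_multiplier = if (isTRUE(as.logical(val)) ||
                            (is.numeric(val) && val != 0)) eff$coefficient else 1
  )
}

#' Build a piecewise-constant parameter trajectory
#'
#' @param breakpoints Segment start times in hours; the first must be 0.
#' @param parameters A single parameter list (recycled) or a list of
#'   parameter lists as returned by [individual_parameters()], one per
#'   segment (clearances in L/day, volumes in L).
#' @return A `parameter_trajectory` data.frame.
#' @export
parameter_trajectory <- function(breakpoints, parameters) {
  stopifnot(length(breakpoints) >= 1, breakpoints[1] == 0,
            !is.unsorted(breakpoints, strictly = TRUE))
  if (!is.null(names(parameters)) && "CL" %in% names(parameters)) {
    parameters <- rep(list(parameters), length(breakpoints))
  }
  stopifnot(length(parameters) == length(breakpoints))
  get <- function(p, nm) as.numeric(p[[nm]] %||% NA_real_)
  tr <- data.frame(
    start = as.numeric(breakpoints),
    CL = vapply(parameters, get, numeric(1), "CL"),
    Vc = vapply(parameters, get, numeric(1), "Vc"),
    Q = vapply(parameters, get, numeric(1), "Q"),
    Vp = vapply(parameters, get, numeric(1), "Vp")
  )
  if (any(!is.finite(tr$CL)) || any(tr$CL <= 0) ||
      any(!is.finite(tr$Vc)) || any(tr$Vc <= 0)) {
    stop("trajectory parameters must be positive in every segment", call. = FALSE)
  }
  structure(tr, class = c("parameter_trajectory", "data.frame"))
}

# propagate amounts over h hours at constant (hourly) parameters and rate
propagate_1cmt <- function(a, h, k10, rate) {
  e <- exp(-k10 * h)
  c(a[1] * e + rate * (1 - e) / k10, 0)
}

propagate_2cmt <- function(a, h, k10, k12, k21, rate) {
  s <- k10 + k12 + k21
  disc <- sqrt(max(s * s - 4 * k10 * k21, 0))
  l1 <- -(s + disc) / 2
  l2 <- -(s - disc) / 2
  if (abs(l1 - l2) < 1e-12 * abs(l1)) l2 <- l1 * (1 - 1e-9)   # guard repeated root
  # E = expm(Mh), S = int_0^h expm(Mu) du via the 2x2 spectral identity
  e1 <- exp(l1 * h); e2 <- exp(l2 * h)
  f1 <- (e1 - 1) / l1; f2 <- (e2 - 1) / l2
  m11 <- -(k10 + k12); m12 <- k21; m21 <- k12; m22 <- -k21
  dl <- l1 - l2
  comb <- function(c1, c2) {
    w1 <- (c1 - c2) / dl
    w2 <- (c1 * (-l2) + c2 * l1) / dl
    # c1*(M - l2 I)/dl - c2*(M - l1 I)/dl  ==  w1*M + w2*I
    matrix(c(w1 * m11 + w2, w1 * m21, w1 * m12, w1 * m22 + w2), 2, 2)
  }
  E <- comb(e1, e2)
  S <- comb(f1, f2)
  as.numeric(E %*% a + S %*% c(rate, 0))
}

#' Concentration-time profile under a dosing schedule
#'
#' @param model A [poppk_model()] (defines the number of compartments).
#' @param doses A data.frame with columns `time` (h), `amt` (mg) and `dur`
#'   (infusion duration, h; 0 means an instantaneous bolus).
#' @param traj A [parameter_trajectory()] covering `[0, max(times)]`.
#' @param times Query times in hours (any order; must be >= 0).
#' @return A data.frame `time`, `conc` (central concentration, ug/mL) in the
#'   order of `times`.
#' @export
concentration_profile <- function(model, doses, traj, times) {
  stopifnot(inherits(traj, "parameter_trajectory"))
  if (any(times < 0)) stop("query times must be >= 0", call. = FALSE)
  two_cmt <- model$n_compartments == 2
  if (two_cmt && (any(!is.finite(traj$Q)) || any(!is.finite(traj$Vp)))) {
    stop("2-compartment model needs Q and Vp in every trajectory segment",
         call. = FALSE)
  }
  if (is.null(doses) || nrow(doses) == 0) {
    return(data.frame(time = times, conc = numeric(length(times))))
  }
  stopifnot(all(c("time", "amt", "dur") %in% names(doses)))
  dose_time <- doses$time; dose_amt <- doses$amt; dose_dur <- doses$dur
  is_inf <- dose_dur > 0
  inf_t0 <- dose_time[is_inf]; inf_t1 <- inf_t0 + dose_dur[is_inf]
  inf_rate <- dose_amt[is_inf] / dose_dur[is_inf]
  bol_t <- dose_time[!is_inf]; bol_amt <- dose_amt[!is_inf]
  t_max <- max(times)
  bounds <- sort(unique(c(0, times, traj$start, dose_time,
                          inf_t1[inf_t1 <= t_max])))
  bounds <- bounds[bounds >= 0 & bounds <= t_max]
  nb <- length(bounds)
  seg <- pmax(findInterval(bounds, traj$start), 1L)
  k10 <- (traj$CL / HOURS_PER_DAY) / traj$Vc
  k12 <- if (two_cmt) (traj$Q / HOURS_PER_DAY) / traj$Vc
  k21 <- if (two_cmt) (traj$Q / HOURS_PER_DAY) / traj$Vp
  vc <- traj$Vc
  a <- c(0, 0)
  conc_at <- numeric(nb)
  for (i in seq_len(nb)) {
    tb <- bounds[i]
    if (length(bol_t)) a[1] <- a[1] + sum(bol_amt[bol_t == tb])
    s <- seg[i]
    conc_at[i] <- a[1] / vc[s]
    if (i == nb) break
    tn <- bounds[i + 1]
    rate <- if (length(inf_t0)) {
      sum(inf_rate[inf_t0 <= tb & inf_t1 >= tn])
    } else 0
    if (two_cmt) {
      a <- propagate_2cmt(a, tn - tb, k10[s], k12[s], k21[s], rate)
    } else {
      a <- propagate_1cmt(a, tn - tb, k10[s], rate)
    }
  }
  data.frame(time = times, conc = conc_at[match(times, bounds)])
}

#' Simulate an observed concentration under the residual-error model
#'
#' `y = f * (1 + eps_prop) + eps_add` with independent normal errors;
#' negative draws are truncated at 0.
#'
#' @param profile_value Model-predicted concentration(s), ug/mL (vectorized).
#' @param error The `error` component of a [poppk_model()] (or any list with
#'   `sigma_prop`, `sigma_add`).
#' @return Simulated concentration(s), ug/mL. Consumes random numbers from
#'   the current RNG stream.
#' @export
simulate_observation <- function(profile_value, error) {
  stopifnot(all(profile_value >= 0))
  n <- length(profile_value)
  eps_p <- if (error$sigma_prop > 0) stats::rnorm(n, 0, error$sigma_prop) else 0
  eps_a <- if (error$sigma_add > 0) stats::rnorm(n, 0, error$sigma_add) else 0
  pmax(profile_value * (1 + eps_p) + eps_a, 0)
}
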