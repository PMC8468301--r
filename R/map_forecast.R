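# map_forecast: empirical Bayes estimation and Bayesian forecasting -------
#
# Given fixed population parameters, the individual random effects (eta,
# and occasion-level kappa where the model carries inter-occasion
# variability) are estimated by minimizing the MAP objective from the
# observations up to and including the anchor concentration. Forward
# predictions then use eta-hat with kappa set to 0: occasion effects are
# informative for the fit but carry no information about future occasions.

patient_doses <- function(data, patient) {
  rows <- data[data$id == patient & data$evid == 1, , drop = FALSE]
  dur <- ifelse(is.na(rows$dur), 0, rows$dur)
  data.frame(time = rows$time, amt = rows$amt, dur = dur)
}

occasion_of <- function(dose_times, t) {
  if (length(dose_times) == 0) return(rep(0L, length(t)))
  findInterval(t, sort(dose_times))
}

model_uses_ada <- function(model) {
  any(vapply(model$covariate_effects,
             function(e) identical(e$covariate, "ada_positive"), logical(1)))
}

# Precompute the eta/kappa-independent part of a patient's trajectory:
# segment breakpoints, occasion index per segment and the "base" parameters
# (typical values times covariate multipliers). Because random effects enter
# multiplicatively, any (eta, kappa) trajectory is the template with its
# columns rescaled — this is what makes repeated objective evaluations and
# VPC replicates cheap.
trajectory_template <- function(model, data, patient,
                                policy = c("full", "locf_at_anchor"),
                                anchor = NULL, t_max) {
  policy <- match.arg(policy)
  rows <- data[data$id == patient, , drop = FALSE]
  need <- model_required_covariates(model)
  dose_t <- sort(rows$time[rows$evid == 1])
  brk <- 0
  if (policy == "full") {
    for (cv in setdiff(need, "ada_positive")) {
      if (cv %in% names(rows)) brk <- c(brk, rows$time[!is.na(rows[[cv]])])
    }
    if (model_uses_ada(model)) brk <- c(brk, rows$time[!is.na(rows$ada)])
  }
  brk <- c(brk, dose_t)                # occasion boundaries
  for (eff in model$covariate_effects) {
    if (eff$form == "piecewise_time_multiplier") {
      brk <- c(brk, eff$reference %||% 0)
    }
  }
  brk <- sort(unique(brk[brk >= 0 & brk <= t_max]))
  base <- lapply(brk, function(s) {
    covs <- list()
    for (cv in need) {
      covs[[cv]] <- if (cv == "ada_positive") {
        tq <- if (policy == "locf_at_anchor") min(s, anchor) else s
        sample_ada_status(data, patient, tq)
      } else {
        covariate_value_at(data, patient, cv, s, policy, anchor)
      }
    }
    individual_parameters(model, covs, eta = NULL, kappa = 0, time = s)
  })
  get <- function(nm) vapply(base, function(p) as.numeric(p[[nm]] %||% NA_real_),
                             numeric(1))
  list(brk = brk,
       occ = as.character(occasion_of(dose_t, brk)),
       CL = get("CL"), Vc = get("Vc"), Q = get("Q"), Vp = get("Vp"))
}

template_trajectory <- function(tpl, eta = NULL, kappa = NULL) {
  cols <- list(start = tpl$brk, CL = tpl$CL, Vc = tpl$Vc,
               Q = tpl$Q, Vp = tpl$Vp)
  if (!is.null(eta)) {
    for (nm in names(eta)) cols[[nm]] <- cols[[nm]] * exp(eta[[nm]])
  }
  if (!is.null(kappa) && length(kappa)) {
    hit <- match(tpl$occ, names(kappa))
    kap <- ifelse(is.na(hit), 0, unlist(kappa)[hit])
    cols$CL <- cols$CL * exp(kap)
  }
  structure(cols, class = c("parameter_trajectory", "data.frame"),
            row.names = seq_along(tpl$brk))
}

#' Piecewise parameter trajectory for one patient
#'
#' Resolves covariates under the requested policy, applies `eta` and
#' occasion-level `kappa`, and places segment boundaries at covariate/ADA
#' measurement times (policy `"full"`), dose times (occasion boundaries)
#' and time-switch thresholds.
#'
#' @param model A [poppk_model()].
#' @param data An [event_table()].
#' @param patient Patient id.
#' @param eta Named eta vector (log scale), or `NULL`.
#' @param kappa Named numeric vector of occasion effects, names being
#'   occasion indices (`"1"` = first dosing interval), or `NULL`.
#' @param policy Covariate policy, `"locf_at_anchor"` or `"full"`.
#' @param anchor Anchor time in hours (needed for `"locf_at_anchor"`).
#' @param t_max Last time the trajectory must cover, hours.
#' @return A [parameter_trajectory()].
#' @export
individual_trajectory <- function(model, data, patient, eta = NULL,
                                  kappa = NULL,
                                  policy = c("full", "locf_at_anchor"),
                                  anchor = NULL, t_max) {
  tpl <- trajectory_template(model, data, patient, policy = policy,
                             anchor = anchor, t_max = t_max)
  template_trajectory(tpl, eta = eta, kappa = kappa)
}

#' Define a Bayesian forecasting task for one patient
#'
#' The anchor is the concentration used for MAP estimation; in the
#' single-sample forecasting setting it is the patient's first retained
#' observation, and all later observations are forecast. Covariates after
#' the anchor are imputed by last observation carried forward
#' (`"locf_at_anchor"`) or taken as measured (`"full"`).
#'
#' @param data A cleaned [event_table()].
#' @param patient Patient id.
#' @param policy Covariate policy for prediction times.
#' @param anchor `"first"` (default), `"last"`, or an observation time in
#'   hours. Observations up to and including the anchor are used for
#'   estimation.
#' @param prediction_times Times to predict at (hours); defaults to the
#'   patient's observation times after the anchor.
#' @return A `forecast_task`.
#' @export
make_forecast_task <- function(data, patient,
                               policy = c("locf_at_anchor", "full"),
                               anchor = "first", prediction_times = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(data, "event_table"))
  rows <- data[data$id == patient, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown patient: ", patient, call. = FALSE)
  o <- rows[rows$evid == 0 & rows$mdv == 0, , drop = FALSE]
  if (nrow(o) == 0) stop("patient ", patient, " has no observations", call. = FALSE)
  anchor_time <- if (identical(anchor, "first")) min(o$time)
    else if (identical(anchor, "last")) max(o$time)
    else as.numeric(anchor)
  if (!any(o$time == anchor_time)) {
    stop("no observation at the requested anchor time", call. = FALSE)
  }
  doses <- patient_doses(data, patient)
  est_obs <- o[o$time <= anchor_time, c("time", "dv")]
  est_obs$occasion <- occasion_of(doses$time, est_obs$time)
  if (is.null(prediction_times)) prediction_times <- o$time[o$time > anchor_time]
  if (any(prediction_times <= anchor_time)) {
    stop("prediction times must lie after the anchor", call. = FALSE)
  }
  structure(list(patient = patient, policy = policy,
                 anchor_time = anchor_time, observations = est_obs,
                 doses = doses, prediction_times = sort(prediction_times),
                 data = data),
            class = "forecast_task")
}

omega_inverse <- function(model) {
  om <- model$random$iiv_omega
  if (is.null(om)) return(NULL)
  inv <- tryCatch(solve(om), error = function(e) {
    stop("inter-individual covariance matrix is singular", call. = FALSE)
  })
  inv
}

#' MAP objective function
#'
#' `sum_j [ (y_j - f_j)^2 / g_j^2 + ln g_j^2 ] + eta' Omega^-1 eta +
#' sum_occ kappa^2 / pi`, with the residual variance
#' `g_j^2 = sigma_add^2 + sigma_prop^2 f_j^2` evaluated at the individual
#' prediction `f_j` (eta-epsilon interaction).
#'
#' @param model A [poppk_model()].
#' @param task A `forecast_task` (its `observations` may be empty for a
#'   prior-only evaluation).
#' @param eta Named eta vector (log scale); `NULL` means all zero.
#' @param kappa Named occasion-effect vector; `NULL` means all zero.
#' @return The scalar objective value.
#' @export
map_objective <- function(model, task, eta = NULL, kappa = NULL) {
  tpl <- if (!is.null(task$observations) && nrow(task$observations) > 0) {
    trajectory_template(model, task$data, task$patient, policy = "full",
                        anchor = task$anchor_time,
                        t_max = max(task$observations$time))
  }
  map_objective_tpl(model, task, tpl, eta, kappa)
}

map_objective_tpl <- function(model, task, tpl, eta = NULL, kappa = NULL) {
  obs <- task$observations
  val <- 0
  if (!is.null(obs) && nrow(obs) > 0) {
    traj <- template_trajectory(tpl, eta = eta, kappa = kappa)
    f <- concentration_profile(model, task$doses, traj, obs$time)$conc
    g2 <- pmax(model$error$sigma_add^2 + model$error$sigma_prop^2 * f^2, 1e-12)
    val <- sum((obs$dv - f)^2 / g2 + log(g2))
  }
  om_inv <- omega_inverse(model)
  if (!is.null(om_inv)) {
    e <- setNames(numeric(nrow(om_inv)), rownames(om_inv))
    if (!is.null(eta)) e[names(eta)] <- eta
    val <- val + as.numeric(e %*% om_inv %*% e)
  } else if (!is.null(eta) && any(eta != 0)) {
    stop("model has no inter-individual variability; eta must be zero",
         call. = FALSE)
  }
  if (!is.null(kappa) && length(kappa)) {
    if (is.null(model$random$iov_pi)) {
      stop("model has no inter-occasion variability; kappa must be empty",
           call. = FALSE)
    }
    val <- val + sum(kappa^2) / model$random$iov_pi
  }
  val
}

MULTISTART_SEED <- 104729L
N_EXTRA_STARTS <- 4L

#' Estimate empirical Bayes random effects for a forecasting task
#'
#' Minimizes [map_objective()] over eta (all parameters carrying
#' inter-individual variability) and the occasion effects of occasions with
#' estimation observations. Local gradient-based optimization from the prior
#' mode plus perturbed multi-starts; the reported estimate is never worse
#' than the prior mode.
#'
#' @param model A [poppk_model()].
#' @param task A `forecast_task` from [make_forecast_task()].
#' @return An `individual_estimate`: `eta_hat`, `kappa_hat` (named by
#'   occasion), `ofv`, `converged`, `patient`.
#' @export
estimate_ebes <- function(model, task) {
  om <- model$random$iiv_omega
  eta_names <- if (is.null(om)) character(0) else rownames(om)
  p <- length(eta_names)
  occasions <- if (!is.null(model$random$iov_pi)) {
    as.character(sort(unique(task$observations$occasion[
      task$observations$occasion > 0])))
  } else character(0)
  q <- length(occasions)
  unpack <- function(theta) {
    list(eta = if (p) setNames(theta[seq_len(p)], eta_names) else NULL,
         kappa = if (q) setNames(theta[p + seq_len(q)], occasions) else NULL)
  }
  tpl <- if (nrow(task$observations) > 0) {
    trajectory_template(model, task$data, task$patient, policy = "full",
                        anchor = task$anchor_time,
                        t_max = max(task$observations$time))
  }
  fn <- function(theta) {
    th <- unpack(theta)
    v <- tryCatch(map_objective_tpl(model, task, tpl, th$eta, th$kappa),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  ofv0 <- fn(numeric(p + q))
  if (p + q == 0) {
    return(structure(list(eta_hat = NULL, kappa_hat = NULL, ofv = ofv0,
                          converged = TRUE, patient = task$patient),
                     class = "individual_estimate"))
  }
  sds <- c(if (p) sqrt(pmax(diag(om), 1e-8)),
           if (q) rep(sqrt(model$random$iov_pi), q))
  starts <- with_seed(MULTISTART_SEED, {
    perturb <- matrix(stats::rnorm(N_EXTRA_STARTS * (p + q)), N_EXTRA_STARTS)
    rbind(0, sweep(perturb, 2, sds, `*`))
  })
  best <- list(value = ofv0, par = numeric(p + q), convergence = 0L)
  any_conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], fn, method = "BFGS",
                   control = list(reltol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (fit$value < best$value) best <- fit
  }
  th <- unpack(best$par)
  structure(list(eta_hat = th$eta, kappa_hat = th$kappa, ofv = best$value,
                 converged = any_conv, patient = task$patient),
            class = "individual_estimate")
}

is_trough_time <- function(doses, t, default_interval = NULL) {
  dt <- sort(doses$time)
  if (length(dt) == 0) return(rep(FALSE, length(t)))
  typical <- if (length(dt) > 1) stats::median(diff(dt)) else
    (default_interval %||% 8 * 7 * HOURS_PER_DAY)
  vapply(t, function(ti) {
    k <- findInterval(ti, dt)
    if (k == 0) return(FALSE)
    t_next <- if (k < length(dt)) dt[k + 1] else dt[k] + typical
    frac <- (ti - dt[k]) / (t_next - dt[k])
    is.finite(frac) && frac >= 0.75
  }, logical(1))
}

#' Forecast concentrations from an individual estimate
#'
#' Predictions use eta-hat with all occasion effects set to 0, covariates
#' resolved under the task's policy. The anchor observation is included as a
#' flagged record (predicted with its estimated occasion effect, since it
#' belongs to a fitted occasion).
#'
#' @param model A [poppk_model()].
#' @param est An `individual_estimate` from [estimate_ebes()].
#' @param task The `forecast_task` the estimate was computed from.
#' @param ada_threshold ADA positivity threshold, U/mL.
#' @return A `prediction_record` data.frame with columns `id`, `time` (h),
#'   `time_after_cmap` (days), `obs`, `pred` (ug/mL), `ada_patient`,
#'   `ada_sample`, `first_ada_time` (days, `NA` if never positive),
#'   `trough`, `anchor`.
#' @export
forecast <- function(model, est, task, ada_threshold = 6.6) {
  stopifnot(inherits(est, "individual_estimate"),
            inherits(task, "forecast_task"))
  pt <- task$prediction_times
  if (any(pt <= task$anchor_time)) {
    stop("prediction times must lie after the anchor", call. = FALSE)
  }
  times <- c(task$anchor_time, pt)
  traj <- individual_trajectory(model, task$data, task$patient,
                                eta = est$eta_hat, kappa = NULL,
                                policy = task$policy,
                                anchor = task$anchor_time, t_max = max(times))
  pred <- concentration_profile(model, task$doses, traj, times)$conc
  # the anchor itself is predicted with its fitted occasion effect
  if (!is.null(est$kappa_hat) && length(est$kappa_hat)) {
    traj_a <- individual_trajectory(model, task$data, task$patient,
                                    eta = est$eta_hat, kappa = est$kappa_hat,
                                    policy = task$policy,
                                    anchor = task$anchor_time,
                                    t_max = task$anchor_time)
    pred[1] <- concentration_profile(model, task$doses, traj_a,
                                     task$anchor_time)$conc
  }
  rows <- task$data[task$data$id == task$patient, , drop = FALSE]
  o <- rows[rows$evid == 0 & rows$mdv == 0, , drop = FALSE]
  obs <- o$dv[match(times, o$time)]
  ada_pat <- patient_ada_positive(task$data, task$patient, ada_threshold)
  first_ada <- first_ada_positive_time(task$data, task$patient, ada_threshold)
  structure(data.frame(
    id = task$patient,
    time = times,
    time_after_cmap = (times - task$anchor_time) / HOURS_PER_DAY,
    obs = obs,
    pred = pred,
    ada_patient = ada_pat,
    ada_sample = vapply(times, function(ti)
      sample_ada_status(task$data, task$patient, ti, ada_threshold), logical(1)),
    first_ada_time = if (is.na(first_ada)) NA_real_ else first_ada / HOURS_PER_DAY,
    trough = is_trough_time(task$doses, times),
    anchor = c(TRUE, rep(FALSE, length(pt))),
    stringsAsFactors = FALSE
  ), class = c("prediction_record", "data.frame"))
}
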