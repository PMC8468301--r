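# synthetic_cohort: virtual IBD cohorts -----------------------------------
#
# A stand-in for a routine therapeutic-drug-monitoring data set of IBD
# patients on infliximab maintenance therapy: ~5.5 mg/kg infusions roughly
# every 8 weeks, sparse sampling at interval midpoints and troughs, ~21% of
# patients developing anti-drug antibodies, and Table-2-style covariate
# distributions. Only marginal summary statistics are emulated; the
# generator makes no attempt to reproduce any real patient.

#' Fully parameterized reference model used throughout tests and examples
#'
#' A two-compartment infusion model with allometric weight scaling, a binary
#' ADA clearance multiplier, log-normal inter-individual variability on
#' clearance, inter-occasion variability on clearance and proportional
#' residual error. Parameter values are plausible for an IgG1 monoclonal
#' antibody in adults; they are this package's own choice, not taken from
#' any published infliximab model.
#'
#' @param ada_cl_multiplier Clearance multiplier while ADA-positive.
#' @param omega_cl SD (log scale) of inter-individual variability on `CL`.
#' @param iov_sd SD (log scale) of inter-occasion variability on `CL`.
#' @param sigma_prop Proportional residual error SD.
#' @param sigma_add Additive residual error SD, ug/mL.
#' @return A [poppk_model()].
#' @export
reference_model <- function(ada_cl_multiplier = 2.0, omega_cl = 0.3,
                            iov_sd = 0.2, sigma_prop = 0.2, sigma_add = 0) {
  poppk_model(
    name = "reference",
    n_compartments = 2,
    typical = list(CL = 0.3, Vc = 3.5, Q = 0.1, Vp = 1.5),
    covariate_effects = list(
      list(target = "CL", covariate = "wt", form = "power",
           coefficient = 0.75, reference = 70),
      list(target = "Vc", covariate = "wt", form = "power",
           coefficient = 1.0, reference = 70),
      list(target = "CL", covariate = "ada_positive",
           form = "binary_multiplier", coefficient = ada_cl_multiplier)
    ),
    iiv_omega = matrix(omega_cl^2, 1, 1, dimnames = list("CL", "CL")),
    iov_pi = iov_sd^2,
    sigma_prop = sigma_prop,
    sigma_add = sigma_add
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a routine-TDM maintenance cohort: median dose 5.5 mg/kg
#' (IQR 5.1-5.9), median dosing interval 8.0 weeks (IQR 7.7-8.6), a median
#' of 2 samples per patient (range 1-12) drawn at interval midpoints and
#' troughs, 21% ADA-positive patients with an exponential onset hazard, and
#' covariates centered on weight 70 kg, albumin 4.35 g/dL, 48% female, 72%
#' Crohn's disease and 16% concomitant immunomodulator use.
#'
#' @param n_patients Number of patients.
#' @param dose_per_kg_median,dose_per_kg_sdlog Log-normal dose level, mg/kg.
#' @param interval_weeks_median,interval_weeks_sdlog Log-normal dosing
#'   interval, weeks.
#' @param samples_mu,samples_size Negative-binomial law of the number of
#'   samples per patient minus one, truncated to a maximum of
#'   `samples_max`; the defaults give median 2.
#' @param samples_max Maximum samples per patient.
#' @param ada_prevalence Fraction of patients developing ADA.
#' @param ada_onset_mean_days Mean of the exponential ADA onset hazard
#'   (truncated so that onset precedes the last sample).
#' @param ada_cl_multiplier Clearance multiplier after ADA onset in the
#'   generating model.
#' @param weight_median_kg,weight_sdlog,weight_range_kg Body weight law.
#' @param albumin_mean,albumin_sd,albumin_range Albumin law, g/dL.
#' @param female_fraction,cd_fraction,imm_fraction Binary covariate rates.
#' @param model Generating [poppk_model()]; defaults to
#'   [reference_model()] with `ada_cl_multiplier`.
#' @param seed Seed for the generator.
#' @export
cohort_config <- function(n_patients = 105,
                          dose_per_kg_median = 5.5, dose_per_kg_sdlog = 0.108,
                          interval_weeks_median = 8.0,
                          interval_weeks_sdlog = 0.082,
                          samples_mu = 2.2, samples_size = 1.3,
                          samples_max = 12,
                          ada_prevalence = 0.21,
                          ada_onset_mean_days = 180,
                          ada_cl_multiplier = 2.0,
                          weight_median_kg = 70, weight_sdlog = 0.2,
                          weight_range_kg = c(47, 115),
                          albumin_mean = 4.35, albumin_sd = 0.35,
                          albumin_range = c(2.5, 5.1),
                          female_fraction = 0.48, cd_fraction = 0.72,
                          imm_fraction = 0.16,
                          model = NULL, seed = 1L) {
  stopifnot(n_patients >= 1,
            ada_prevalence >= 0 && ada_prevalence <= 1,
            female_fraction >= 0 && female_fraction <= 1,
            cd_fraction >= 0 && cd_fraction <= 1,
            imm_fraction >= 0 && imm_fraction <= 1,
            weight_range_kg[1] <= weight_median_kg,
            weight_median_kg <= weight_range_kg[2],
            samples_max >= 1)
  structure(c(as.list(environment())), class = "cohort_config")
}

rlnorm_trunc <- function(n, median, sdlog, range = NULL) {
  x <- stats::rlnorm(n, log(median), sdlog)
  if (!is.null(range)) x <- pmin(pmax(x, range[1]), range[2])
  x
}

#' Generate a synthetic TDM cohort and its ground truth
#'
#' @param cfg A [cohort_config()].
#' @return A list with `data` (an [event_table()] with dose and observation
#'   rows, covariates and ADA measurements) and `truth` (per-patient true
#'   `eta`, per-occasion `kappa` and ADA onset time in hours, `NA` for
#'   patients never developing ADA).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  model <- cfg$model %||% reference_model(ada_cl_multiplier = cfg$ada_cl_multiplier)
  om <- model$random$iiv_omega
  chol_om <- if (!is.null(om)) chol(om)
  iov <- model$random$iov_pi
  with_seed(derive_seed(cfg$seed, "cohort"), {
    rows <- vector("list", cfg$n_patients)
    truth <- vector("list", cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      id <- sprintf("S%03d", i)
      wt <- rlnorm_trunc(1, cfg$weight_median_kg, cfg$weight_sdlog,
                         cfg$weight_range_kg)
      alb <- min(max(stats::rnorm(1, cfg$albumin_mean, cfg$albumin_sd),
                     cfg$albumin_range[1]), cfg$albumin_range[2])
      crp <- min(stats::rlnorm(1, log(0.29), 1.0), 7.5)
      female <- stats::rbinom(1, 1, cfg$female_fraction)
      cd <- stats::rbinom(1, 1, cfg$cd_fraction)
      imm <- stats::rbinom(1, 1, cfg$imm_fraction)
      hbi <- min(stats::rnbinom(1, size = 1.2, mu = 2), 18)

      n_obs <- min(1L + stats::rnbinom(1, size = cfg$samples_size,
                                       mu = cfg$samples_mu), cfg$samples_max)
      interval <- rlnorm_trunc(1, cfg$interval_weeks_median,
                               cfg$interval_weeks_sdlog) * 7 * HOURS_PER_DAY
      amt <- round(rlnorm_trunc(1, cfg$dose_per_kg_median,
                                cfg$dose_per_kg_sdlog) * wt)
      n_cycles <- max(4L, ceiling(n_obs / 2) + 2L)
      dose_t <- (seq_len(n_cycles) - 1) * interval +
        c(0, stats::rnorm(n_cycles - 1, 0, HOURS_PER_DAY))
      dose_t <- cummax(pmax(dose_t, 0))
      doses <- data.frame(time = dose_t, amt = amt, dur = 2)

      # midpoint/trough sampling in randomly chosen dosing intervals
      cyc <- sort(sample(seq_len(n_cycles - 1), n_obs, replace = TRUE))
      midpoint <- stats::runif(n_obs) < 0.5
      t_obs <- ifelse(midpoint,
                      dose_t[cyc] + 0.5 * interval +
                        stats::rnorm(n_obs, 0, 1.5 * HOURS_PER_DAY),
                      dose_t[cyc + 1] - stats::runif(n_obs, 1, 24))
      t_obs <- sort(pmax(pmin(t_obs, dose_t[cyc + 1] - 0.5), dose_t[cyc] + 4))

      ada_pos <- stats::rbinom(1, 1, cfg$ada_prevalence) == 1
      onset <- NA_real_
      if (ada_pos) {
        # truncated exponential onset: positivity must be observable
        tmax <- max(t_obs)
        u <- stats::runif(1)
        rate <- 1 / (cfg$ada_onset_mean_days * HOURS_PER_DAY)
        onset <- -log(1 - u * (1 - exp(-rate * tmax))) / rate
      }
      ada_level <- ifelse(!ada_pos | t_obs < onset,
                          stats::runif(n_obs, 0, 3.13),
                          stats::rlnorm(n_obs, log(30), 0.6) + 6.6)

      eta <- if (!is.null(om)) {
        setNames(as.numeric(crossprod(chol_om, stats::rnorm(nrow(om)))),
                 rownames(om))
      }
      occs <- as.character(seq_len(n_cycles))
      kappa <- if (!is.null(iov)) {
        setNames(stats::rnorm(n_cycles, 0, sqrt(iov)), occs)
      }

      # the true clearance switch follows the latent onset, not the assay
      covs_const <- list(wt = wt, alb = alb, crp = crp, sex = female,
                         cd = cd, imm = imm, hbi = hbi)
      brk <- sort(unique(c(0, dose_t, if (ada_pos) onset)))
      brk <- brk[brk <= max(t_obs)]
      segs <- lapply(brk, function(s) {
        covs <- covs_const
        covs$ada_positive <- ada_pos && s >= onset
        occ <- as.character(occasion_of(dose_t, s))
        kap <- if (!is.null(kappa) && occ %in% names(kappa)) kappa[[occ]] else 0
        individual_parameters(model, covs, eta = eta, kappa = kap, time = s)
      })
      traj <- parameter_trajectory(brk, segs)
      f <- concentration_profile(model, doses, traj, t_obs)$conc
      dv <- simulate_observation(f, model$error)

      ptab <- event_table(data.frame(
        id = id,
        time = c(dose_t, t_obs),
        evid = c(rep(1L, n_cycles), rep(0L, n_obs)),
        amt = c(rep(amt, n_cycles), rep(NA, n_obs)),
        dur = c(rep(2, n_cycles), rep(NA, n_obs)),
        dv = c(rep(NA, n_cycles), dv),
        mdv = c(rep(1L, n_cycles), rep(0L, n_obs)),
        blq = FALSE,
        ada = c(rep(NA, n_cycles), ada_level),
        wt = wt, alb = alb, crp = crp, sex = female, cd = cd,
        imm = imm, hbi = hbi
      ))
      rows[[i]] <- as.data.frame(ptab)
      truth[[i]] <- list(id = id, eta = eta, kappa = kappa,
                         ada_onset = onset)
    }
    data <- event_table(do.call(rbind, rows))
    names(truth) <- vapply(truth, `[[`, character(1), "id")
    list(data = data, truth = truth)
  })
}

#' Deterministic fixture for the exclusion cascade
#'
#' A 124-patient, 400-concentration event table engineered so that the
#' cascade removes, in order: 11 patients whose dosing history is unusable
#' (33 samples), 3 BLQ concentrations, 28 pharmacokinetically implausible
#' concentrations, and 8 patients left without informative concentrations —
#' retaining 336 concentrations from 105 patients. The 8 uninformative
#' patients comprise 3 whose only sample is BLQ and 5 with dosing records
#' but no concentration samples.
#'
#' @return An [event_table()].
#' @export
generate_cascade_fixture <- function() {
  interval <- 8 * 7 * HOURS_PER_DAY
  mk_patient <- function(id, n_obs, with_doses = TRUE, blq_only = FALSE,
                         n_implausible = 0) {
    n_cycles <- max(3L, ceiling(n_obs / 2) + 1L)
    dose_t <- (seq_len(n_cycles) - 1) * interval
    obs_t <- numeric(0); obs_c <- numeric(0)
    if (blq_only) {
      obs_t <- dose_t[1] + interval / 2
      obs_c <- 1e-3                     # below 2.68 ng/mL
    } else if (n_obs > 0) {
      cyc <- rep(seq_len(n_cycles - 1), length.out = n_obs)
      pos_in_cycle <- as.integer(stats::ave(cyc, cyc, FUN = seq_along))
      frac <- 0.35 + 0.3 * (pos_in_cycle - 1) / max(pos_in_cycle)
      obs_t <- dose_t[cyc] + frac * interval
      obs_c <- 28 * exp(-0.002 * (obs_t - dose_t[cyc])) + 0.3 * cyc
      ord <- order(obs_t)
      obs_t <- obs_t[ord]; obs_c <- obs_c[ord]
    }
    if (n_implausible > 0) {
      # later, non-decreasing sample >= 7 days after the first of interval 1
      t0 <- obs_t[1]
      add_t <- t0 + 8 * HOURS_PER_DAY
      add_c <- obs_c[1] + 0.5
      obs_t <- c(obs_t, add_t); obs_c <- c(obs_c, add_c)
    }
    n_o <- length(obs_t)
    df <- data.frame(
      id = id,
      time = c(if (with_doses) dose_t, obs_t),
      evid = c(if (with_doses) rep(1L, n_cycles), rep(0L, n_o)),
      amt = c(if (with_doses) rep(385, n_cycles), rep(NA, n_o)),
      dur = c(if (with_doses) rep(2, n_cycles), rep(NA, n_o)),
      dv = c(if (with_doses) rep(NA, n_cycles), obs_c),
      mdv = c(if (with_doses) rep(1L, n_cycles), rep(0L, n_o)),
      blq = FALSE,
      ada = NA_real_,
      wt = 70, alb = 4.35, crp = 0.3, sex = 0, cd = 1, imm = 0, hbi = 1
    )
    df
  }
  # retained patients: sample counts with median 2, range 1-12, total 336
  counts <- c(rep(1, 10), rep(2, 65), rep(6, 27), 10, rep(12, 2))
  stopifnot(length(counts) == 105, sum(counts) == 336)
  implausible_flags <- c(rep(0, 77), rep(1, 28))   # the 28 multi-sample patients
  stopifnot(all(counts[implausible_flags == 1] >= 2))
  rows <- list()
  k <- 0
  for (i in seq_along(counts)) {
    k <- k + 1
    rows[[k]] <- mk_patient(sprintf("P%03d", k), counts[i],
                            n_implausible = implausible_flags[i])
  }
  for (i in seq_len(11)) {             # unusable dosing: observations, no doses
    k <- k + 1
    rows[[k]] <- mk_patient(sprintf("P%03d", k), 3, with_doses = FALSE)
  }
  for (i in seq_len(3)) {              # single BLQ sample
    k <- k + 1
    rows[[k]] <- mk_patient(sprintf("P%03d", k), 1, blq_only = TRUE)
  }
  for (i in seq_len(5)) {              # dosing records, no samples
    k <- k + 1
    rows[[k]] <- mk_patient(sprintf("P%03d", k), 0)
  }
  event_table(do.call(rbind, rows))
}
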