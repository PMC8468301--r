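# Shared fixtures and independent oracles used across test files.

# Minimal one-compartment model: CL 2.4 L/day, Vc 10 L  =>  k = 0.01 /h.
toy_1cmt <- function(omega_cl = NULL, omega_vc = NULL, sigma_prop = 0.2,
                     sigma_add = 0, iov_sd = NULL) {
  pars <- c(CL = omega_cl, Vc = omega_vc)
  om <- if (length(pars)) diag(pars, nrow = length(pars)) |>
    `dimnames<-`(list(names(pars), names(pars)))
  poppk_model("toy1", 1, list(CL = 2.4, Vc = 10),
              iiv_omega = om,
              iov_pi = if (!is.null(iov_sd)) iov_sd^2,
              sigma_prop = sigma_prop, sigma_add = sigma_add)
}

# One patient, one bolus dose, observations at given times/values.
toy_event_table <- function(obs_time, obs_dv, dose_amt = 100, dose_time = 0,
                            dose_dur = 0, ada = NA_real_, id = "T1", ...) {
  n <- length(obs_time)
  extras <- list(...)
  df <- data.frame(
    id = id,
    time = c(dose_time, obs_time),
    evid = c(rep(1L, length(dose_time)), rep(0L, n)),
    amt = c(rep(dose_amt, length.out = length(dose_time)), rep(NA, n)),
    dur = c(rep(dose_dur, length.out = length(dose_time)), rep(NA, n)),
    dv = c(rep(NA, length(dose_time)), obs_dv),
    mdv = c(rep(1L, length(dose_time)), rep(0L, n)),
    blq = FALSE,
    ada = c(rep(NA, length(dose_time)), rep(ada, length.out = n))
  )
  for (nm in names(extras)) df[[nm]] <- extras[[nm]]
  event_table(df)
}

# Closed-form 1-CMT bolus concentration (independent of the engine).
conc_1cmt_bolus <- function(t, dose, CL_day, Vc, t_dose = 0) {
  k <- CL_day / 24 / Vc
  ifelse(t < t_dose, 0, dose / Vc * exp(-k * (t - t_dose)))
}

# ODE oracle for the 2-CMT infusion model: integrates segment by segment,
# restarting at every dose start/end so the solver cannot step over a
# forcing discontinuity. Requires deSolve.
ode_oracle_2cmt <- function(doses, pars, times) {
  k10 <- pars$CL / 24 / pars$Vc
  k12 <- pars$Q / 24 / pars$Vc
  k21 <- pars$Q / 24 / pars$Vp
  rhs <- function(t, y, rate) {
    list(c(-(k10 + k12) * y[1] + k21 * y[2] + rate,
           k12 * y[1] - k21 * y[2]))
  }
  cuts <- sort(unique(c(0, doses$time, doses$time + doses$dur, times)))
  y <- c(0, 0)
  out_c <- numeric(length(times))
  for (i in seq_len(length(cuts) - 1)) {
    t0 <- cuts[i]; t1 <- cuts[i + 1]
    rate <- sum(doses$amt / doses$dur *
                  (doses$time <= t0 & doses$time + doses$dur >= t1))
    sol <- deSolve::ode(y, c(t0, t1), function(t, y, p) rhs(t, y, rate),
                        NULL, rtol = 1e-12, atol = 1e-12)
    y <- as.numeric(sol[nrow(sol), 2:3])
    hit <- which(times == t1)
    if (length(hit)) out_c[hit] <- y[1] / pars$Vc
  }
  out_c
}

small_cohort <- function(n = 20, seed = 42, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}
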