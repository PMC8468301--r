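# a forecast task whose estimation set is empty, for prior-only objectives
prior_only_task <- function(data, patient = "T1") {
  task <- make_forecast_task(data, patient)
  task$observations <- task$observations[0, , drop = FALSE]
  task
}

test_that("the MAP objective reduces to the prior without observations", {
  m <- toy_1cmt(omega_cl = 0.09)
  tab <- toy_event_table(obs_time = 24, obs_dv = 8)
  task <- prior_only_task(tab)
  expect_equal(map_objective(m, task, eta = c(CL = 0)), 0)
  expect_equal(map_objective(m, task), 0)
  # quadratic prior: eta' Omega^-1 eta
  expect_equal(map_objective(m, task, eta = c(CL = 0.3)), 0.3^2 / 0.09)
  # occasion effect prior: kappa^2 / pi
  m_iov <- toy_1cmt(omega_cl = 0.09, iov_sd = 0.2)
  expect_equal(map_objective(m_iov, task, eta = c(CL = 0.1),
                             kappa = c(`1` = 0.15)),
               0.1^2 / 0.09 + 0.15^2 / 0.04, tolerance = 1e-12)
})

test_that("the MAP objective matches an independent hand evaluation", {
  m <- toy_1cmt(omega_cl = 0.09, sigma_prop = 0.2, sigma_add = 0.1)
  tab <- toy_event_table(obs_time = 24, obs_dv = 9, dose_amt = 100)
  task <- make_forecast_task(tab, "T1")
  eta <- c(CL = 0.1)
  # independent evaluation from the closed-form 1-CMT solution
  f <- conc_1cmt_bolus(24, 100, 2.4 * exp(0.1), 10)
  g2 <- 0.1^2 + 0.2^2 * f^2
  by_hand <- (9 - f)^2 / g2 + log(g2) + 0.1^2 / 0.09
  expect_equal(map_objective(m, task, eta = eta), by_hand, tolerance = 1e-10)
})

test_that("a vanishing prior variance pins the estimate at zero", {
  m <- toy_1cmt(omega_cl = 1e-8)
  tab <- toy_event_table(obs_time = 24, obs_dv = 30)   # data pull far from 0
  est <- estimate_ebes(m, make_forecast_task(tab, "T1"))
  expect_lt(abs(est$eta_hat[["CL"]]), 1e-3)
})

test_that("noise-free data with a diffuse prior recovers the true eta", {
  m <- toy_1cmt(omega_cl = 100, sigma_prop = 0.05)
  eta_true <- 0.4
  t_obs <- c(24, 240, 480, 672)
  dv <- conc_1cmt_bolus(t_obs, 100, 2.4 * exp(eta_true), 10)
  tab <- toy_event_table(obs_time = t_obs, obs_dv = dv)
  est <- estimate_ebes(m, make_forecast_task(tab, "T1", anchor = "last"))
  expect_true(est$converged)
  expect_lt(abs(est$eta_hat[["CL"]] - eta_true), 1e-3)
})

test_that("the optimizer agrees with a dense grid search on a 2-parameter toy", {
  m <- toy_1cmt(omega_cl = 0.09, omega_vc = 0.04, sigma_prop = 0.15)
  t_obs <- c(24, 120)
  dv <- c(8.1, 2.4)
  tab <- toy_event_table(obs_time = t_obs, obs_dv = dv)
  task <- make_forecast_task(tab, "T1", anchor = "last")
  est <- estimate_ebes(m, task)

  # independent oracle: closed-form objective on a step-0.001 grid
  step <- 1e-3
  g <- as.matrix(expand.grid(eCL = seq(-0.3, 0.3, by = step),
                             eVc = seq(-0.3, 0.3, by = step)))
  obj <- numeric(nrow(g))
  for (j in seq_along(t_obs)) {
    f <- (100 / (10 * exp(g[, 2]))) *
      exp(-(2.4 * exp(g[, 1])) / 24 / (10 * exp(g[, 2])) * t_obs[j])
    g2 <- 0.15^2 * f^2
    obj <- obj + (dv[j] - f)^2 / g2 + log(g2)
  }
  obj <- obj + g[, 1]^2 / 0.09 + g[, 2]^2 / 0.04
  grid_min <- g[which.min(obj), ]
  expect_lt(abs(est$eta_hat[["CL"]] - grid_min[["eCL"]]), 2 * step)
  expect_lt(abs(est$eta_hat[["Vc"]] - grid_min[["eVc"]]), 2 * step)
})

test_that("the estimate is never worse than the prior mode", {
  coh <- small_cohort(8, seed = 17)
  m <- reference_model()
  for (p in unique(coh$data$id)) {
    task <- make_forecast_task(coh$data, p)
    est <- estimate_ebes(m, task)
    expect_lte(est$ofv, map_objective(m, task) + 1e-8)
  }
})

test_that("shrinkage: larger residual error pulls eta toward zero", {
  tab <- toy_event_table(obs_time = 24, obs_dv = 14)
  norms <- vapply(c(0.1, 0.2, 0.4, 0.8), function(s) {
    m <- toy_1cmt(omega_cl = 0.25, sigma_prop = s)
    abs(estimate_ebes(m, make_forecast_task(tab, "T1"))$eta_hat[["CL"]])
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("forecasts use eta-hat with occasion effects zeroed", {
  m <- reference_model()
  coh <- small_cohort(6, seed = 23)
  d <- coh$data
  p <- unique(d$id)[1]
  task <- make_forecast_task(d, p)
  est <- estimate_ebes(m, task)
  fc <- forecast(m, est, task)
  # prediction rows equal the engine profile with eta-hat and kappa = 0
  traj <- individual_trajectory(m, d, p, eta = est$eta_hat, kappa = NULL,
                                policy = "locf_at_anchor",
                                anchor = task$anchor_time,
                                t_max = max(fc$time))
  direct <- concentration_profile(m, patient_doses(d, p), traj, fc$time)$conc
  expect_equal(fc$pred[!fc$anchor], direct[!fc$anchor], tolerance = 1e-12)
  expect_equal(sum(fc$anchor), 1L)
  expect_true(all(fc$time_after_cmap[!fc$anchor] > 0))
})

test_that("doubling every dose doubles the forecast (linear kinetics)", {
  m <- reference_model()
  coh <- small_cohort(6, seed = 29)
  p <- unique(coh$data$id)[2]
  task <- make_forecast_task(coh$data, p)
  est <- estimate_ebes(m, task)
  fc <- forecast(m, est, task)
  doubled <- as.data.frame(coh$data)
  doubled$amt <- doubled$amt * 2
  task2 <- make_forecast_task(event_table(doubled), p)
  fc2 <- forecast(m, est, task2)
  expect_equal(fc2$pred, 2 * fc$pred, tolerance = 1e-10)
})

test_that("LOCF freezes the ADA effect at its anchor value", {
  m <- reference_model()
  # ADA turns positive only after the anchor observation
  tab <- toy_event_table(obs_time = c(672, 1500, 2000),
                         obs_dv = c(12, 6, 4),
                         dose_time = c(0, 1344), dose_amt = 350, dose_dur = 2,
                         ada = NA, wt = 70)
  tab$ada[tab$evid == 0] <- c(1.0, 30.0, 45.0)
  task_locf <- make_forecast_task(tab, "T1", policy = "locf_at_anchor")
  est <- estimate_ebes(m, task_locf)
  fc_locf <- forecast(m, est, task_locf)

  # ADA-negative twin: same data, never positive
  tab_neg <- as.data.frame(tab)
  tab_neg$ada[tab_neg$evid == 0] <- 1.0
  task_neg <- make_forecast_task(event_table(tab_neg), "T1", policy = "full")
  fc_neg <- forecast(m, est, task_neg)
  expect_equal(fc_locf$pred, fc_neg$pred, tolerance = 1e-12)

  # fully informed covariates react to the ADA switch: the concentration at
  # the switch itself is unchanged, later ones decay faster
  task_full <- make_forecast_task(tab, "T1", policy = "full")
  fc_full <- forecast(m, est, task_full)
  at_switch <- fc_full$time == 1500
  expect_equal(fc_full$pred[at_switch], fc_locf$pred[at_switch],
               tolerance = 1e-12)
  expect_lt(fc_full$pred[fc_full$time == 2000],
            fc_locf$pred[fc_locf$time == 2000])
})
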