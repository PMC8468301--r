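test_that("individual parameters combine covariates and random effects", {
  m <- reference_model()
  # reference weight, no ADA, no random effects: typical values unchanged
  p <- individual_parameters(m, list(wt = 70, ada_positive = FALSE))
  expect_equal(p$CL, 0.3)
  expect_equal(p$Vc, 3.5)
  # allometric multiplier at twice the reference weight
  p2 <- individual_parameters(m, list(wt = 140, ada_positive = FALSE))
  expect_equal(p2$CL / 0.3, 2^0.75, tolerance = 1e-12)
  expect_equal(p2$Vc / 3.5, 2, tolerance = 1e-12)
  # eta and kappa multiply clearance on the log scale
  p3 <- individual_parameters(m, list(wt = 70, ada_positive = FALSE),
                              eta = c(CL = 0.2), kappa = 0.1)
  expect_equal(p3$CL, 0.3 * exp(0.3), tolerance = 1e-12)
  # binary ADA multiplier
  p4 <- individual_parameters(m, list(wt = 70, ada_positive = TRUE))
  expect_equal(p4$CL, 0.3 * 2.0, tolerance = 1e-12)
  expect_error(individual_parameters(m, list(ada_positive = FALSE)), "wt")
})

test_that("profiles are zero without doses and before the first dose", {
  m <- toy_1cmt()
  traj <- parameter_trajectory(0, list(CL = 2.4, Vc = 10))
  prof <- concentration_profile(m, NULL, traj, c(0, 10, 100))
  expect_equal(prof$conc, c(0, 0, 0))
  doses <- data.frame(time = 48, amt = 100, dur = 2)
  prof2 <- concentration_profile(m, doses, traj, c(0, 24, 47.9, 50, 100))
  expect_equal(prof2$conc[1:3], c(0, 0, 0))
  expect_gt(prof2$conc[4], 0)
  expect_error(concentration_profile(m, doses, traj, -1), ">= 0")
})

test_that("linearity: dose proportionality and superposition are exact", {
  m <- reference_model()
  traj <- parameter_trajectory(0, list(CL = 0.3, Vc = 3.5, Q = 0.1, Vp = 1.5))
  d1 <- data.frame(time = 0, amt = 385, dur = 2)
  d2 <- data.frame(time = 1344, amt = 200, dur = 1)
  times <- c(1, 5, 100, 1000, 1344.5, 1400, 2500)
  c1 <- concentration_profile(m, d1, traj, times)$conc
  c2 <- concentration_profile(m, d2, traj, times)$conc
  both <- concentration_profile(m, rbind(d1, d2), traj, times)$conc
  expect_equal(both, c1 + c2, tolerance = 1e-12)
  doubled <- d1; doubled$amt <- 2 * d1$amt
  expect_equal(concentration_profile(m, doubled, traj, times)$conc,
               2 * c1, tolerance = 1e-12)
})

test_that("2-CMT infusion closed form matches adaptive ODE integration", {
  m <- reference_model()
  pars <- list(CL = 0.3, Vc = 3.5, Q = 0.1, Vp = 1.5)
  traj <- parameter_trajectory(0, pars)
  doses <- data.frame(time = c(0, 1344, 2688), amt = c(385, 385, 420),
                      dur = c(2, 2, 1.5))
  set.seed(11)
  times <- sort(stats::runif(50, 0.1, 3500))
  engine <- concentration_profile(m, doses, traj, times)$conc
  oracle <- ode_oracle_2cmt(doses, pars, times)
  expect_lt(max(abs(engine - oracle) / oracle), 1e-6)
})

test_that("1-CMT repeated-bolus trough matches the steady-state closed form", {
  m <- toy_1cmt()
  tau <- 1344; D <- 350; n_dose <- 60
  traj <- parameter_trajectory(0, list(CL = 2.4, Vc = 10))
  doses <- data.frame(time = (0:(n_dose - 1)) * tau, amt = D, dur = 0)
  trough <- concentration_profile(m, doses, traj, n_dose * tau - 1e-9)$conc
  k <- 2.4 / 24 / 10
  expect_equal(trough, (D / 10) * exp(-k * tau) / (1 - exp(-k * tau)),
               tolerance = 1e-9)
})

test_that("the 2-CMT profile converges to 1-CMT as Q -> 0", {
  m2 <- reference_model()
  m1 <- toy_1cmt()
  doses <- data.frame(time = 0, amt = 385, dur = 2)
  times <- c(1, 24, 240, 1000)
  tr1 <- parameter_trajectory(0, list(CL = 0.3, Vc = 3.5))
  c1 <- concentration_profile(m1, doses, tr1, times)$conc
  tr2 <- parameter_trajectory(0, list(CL = 0.3, Vc = 3.5, Q = 1e-10, Vp = 1.5))
  c2 <- concentration_profile(m2, doses, tr2, times)$conc
  expect_equal(c2, c1, tolerance = 1e-7)
})

test_that("a breakpoint without a parameter change leaves the profile unchanged", {
  m <- reference_model()
  pars <- list(CL = 0.3, Vc = 3.5, Q = 0.1, Vp = 1.5)
  doses <- data.frame(time = 0, amt = 385, dur = 2)
  times <- c(10, 300, 700, 1300)
  unsplit <- concentration_profile(m, doses, parameter_trajectory(0, pars),
                                   times)$conc
  split <- concentration_profile(m, doses,
                                 parameter_trajectory(c(0, 500), list(pars, pars)),
                                 times)$conc
  expect_equal(split, unsplit, tolerance = 1e-12)
})

test_that("residual-error simulation has the specified moments", {
  err0 <- list(sigma_prop = 0, sigma_add = 0)
  expect_equal(simulate_observation(c(0, 5, 10), err0), c(0, 5, 10))
  expect_equal(simulate_observation(0, list(sigma_prop = 0.3, sigma_add = 0)), 0)
  set.seed(101)
  y <- simulate_observation(rep(10, 1e5), list(sigma_prop = 0.2, sigma_add = 0))
  expect_equal(stats::sd(y), 2.0, tolerance = 0.02)
  expect_true(all(y >= 0))
})
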