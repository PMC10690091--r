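test_that("ER stays at baseline without drug and matches the analytic steady state", {
  p <- er_params(kout = log(2) / 3, smax = 9, sc50 = 0.4)
  no_drug <- simulate_er(p, 0, times = c(0, 4, 12, 48))
  expect_equal(no_drug$rel_er, rep(1, 4), tolerance = 1e-9)

  # constant exposure: endpoint matches the closed form across a grid
  for (smax in c(1, 4, 9, 19)) {
    for (ratio in c(0.1, 1, 10)) {
      pp <- er_params(kout = 0.3, smax = smax, sc50 = 0.5)
      end <- simulate_er(pp, 0.5 * ratio, times = 200)$rel_er
      expect_equal(end, er_ss_oracle(1, smax, ratio), tolerance = 1e-6)
    }
  }
  # the documented example: Cu = sc50, smax = 9 -> e0/5.5
  end <- simulate_er(p, 0.4, times = 150)$rel_er
  expect_equal(end, 1 / 5.5, tolerance = 1e-6)
})

test_that("an R-function exposure agrees with the compiled exposure path", {
  p <- er_params(kout = log(2) / 3, smax = 9, sc50 = 0.4)
  pk <- pk_params(1, log(2) / 5, 5, 0.01)
  reg <- dose_regimen(10, 24, 3)
  fast <- free_conc_fn(pk, reg)
  slow <- function(t) fast(t)   # plain closure, forces the R integrator path
  t <- c(0, 0.5, 1, 2, 6, 12, 24, 30, 48)
  expect_equal(simulate_er(p, fast, t)$rel_er,
               simulate_er(p, slow, t)$rel_er, tolerance = 1e-7)
})

test_that("higher exposure never yields higher ER", {
  p <- er_params(kout = 0.25, smax = 9, sc50 = 0.4)
  t <- seq(0, 48, by = 1)
  lo <- simulate_er(p, 0.2, t)$rel_er
  hi <- simulate_er(p, 2.0, t)$rel_er
  expect_true(all(hi <= lo + 1e-9))
})

test_that("steady-state suppression is bounded, monotone and matches closed forms", {
  p <- er_params(kout = 0.2, smax = 9, sc50 = 0.4)
  expect_equal(steady_state_suppression(p, 0), 0)
  expect_equal(steady_state_suppression(p, 1e12), 9 / 10, tolerance = 1e-9)
  expect_equal(steady_state_suppression(p, 0.4), 1 - 1 / 5.5, tolerance = 1e-12)
  cu <- c(0, 0.1, 0.4, 1, 10, 100)
  s <- steady_state_suppression(p, cu)
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s <= 9 / 10))
})

test_that("half-life estimation is exact on noiseless decay and robust to noise", {
  t <- c(0, 0.25, 0.5, 1, 2, 4)
  lev <- exp(-log(2) * t / 0.5)
  est <- estimate_half_life(t, lev)
  expect_equal(est$half_life, 0.5, tolerance = 1e-6)

  expect_error(estimate_half_life(t, rep(1, length(t))), "no measurable decay")
  expect_error(estimate_half_life(c(0, 1), c(1, 0.5)), "3 timepoints")

  course <- simulate_decay_course(3, times = c(0, 1, 2, 4, 8, 12),
                                  noise_model(er_cv = 0.10, seed = 1))
  est <- estimate_half_life(course)
  expect_lt(abs(est$half_life - 3) / 3, 0.15)
})

test_that("decay under constant drug refits to ln2/(kout*stimulation)", {
  # strong stimulation makes the floor negligible so the log-linear
  # estimator applies; expected half-life is ln2 / (kout * (1 + smax))
  p <- er_params(kout = 0.2, smax = 999, sc50 = 0.5)
  k <- p$kout * (1 + p$smax)
  expected <- log(2) / k
  t <- seq(0, 2 * expected, length.out = 6)
  course <- simulate_er(p, 1e9, t, rtol = 1e-10, atol = 1e-12)
  est <- estimate_half_life(course)
  expect_lt(abs(est$half_life - expected) / expected, 0.01)
})

test_that("PK/PD fit recovers generating parameters from a noiseless study", {
  des <- four_dose_design(n_per_arm = 2)
  truth <- default_truth()
  b <- simulate_study(des, truth, noise_model(0, 0, 0, 0, seed = 1))
  fit <- fit_er_pkpd(b$er, truth$pk, arm_regimens(des), rtol = 1e-8)
  expect_true(fit$converged)
  est <- coef(fit)
  expect_equal(est[["kout"]], truth$er$kout, tolerance = 1e-3)
  expect_equal(est[["smax"]], truth$er$smax, tolerance = 1e-3)
  expect_equal(est[["sc50"]], truth$er$sc50, tolerance = 1e-3)
})

test_that("PK/PD fit refuses unidentifiable designs", {
  truth <- default_truth()
  des1 <- study_design(list(vehicle = NULL, d10 = dose_regimen(10)),
                       n_per_arm = 2, duration_days = 7)
  b1 <- simulate_study(des1, truth, noise_model(seed = 1))
  expect_error(fit_er_pkpd(b1$er, truth$pk, arm_regimens(des1)),
               "unidentifiable")
  veh <- b1$er[b1$er$arm == "vehicle", ]
  expect_error(fit_er_pkpd(veh, truth$pk, list(vehicle = NULL)),
               "unidentifiable")
})

test_that("average suppression is zero without drug, matches the infusion limit, and rises with dose", {
  truth <- default_truth()
  er <- truth$er; pk <- truth$pk
  expect_equal(average_suppression(er, pk, dose_regimen(0)), 0)

  # near-constant infusion: rapid small doses whose steady-state average
  # free concentration equals sc50 reproduce the closed-form 1 - 1/5.5
  interval <- 0.1
  dose <- er$sc50 * interval * pk$ke * pk$vd_over_f * 452 / (pk$fu * 1e6)
  reg <- dose_regimen(dose, interval, 1, molecular_weight = 452)
  avg <- average_suppression(er, pk, reg, n_grid = 101)
  expect_equal(avg, 1 - 1 / 5.5, tolerance = 1e-2)

  avgs <- vapply(c(1, 3, 10, 30),
                 function(d) average_suppression(er, pk, dose_regimen(d, 24, 14)),
                 0)
  expect_true(all(diff(avgs) > 0))
  expect_true(all(avgs >= 0 & avgs <= er$smax / (1 + er$smax)))
})
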