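test_that("vehicle growth follows the exponential model exactly", {
  gp <- growth_params(b0 = 0.02)
  tv <- simulate_tumor(gp, NULL, days = c(0, 7, 14), v0 = 200)
  expect_equal(tv$volume_mm3, 200 * 10^(0.02 * c(0, 7, 14)), tolerance = 1e-12)
  expect_equal(tv$volume_mm3[3], 381.1, tolerance = 1e-3)
})

test_that("the ER-growth link reduces to known limits", {
  days <- c(0, 7, 14, 21)
  flat_zero <- data.frame(time_h = c(0, 600), rel_er = c(0, 0))
  # full suppression with bkill = 2*b0 gives net regression at rate -b0
  gp <- growth_params(b0 = 0.02, bkill = 0.04, gamma = 1)
  tv <- simulate_tumor(gp, flat_zero, days, v0 = 200)
  expect_equal(tv$volume_mm3, 200 * 10^(-0.02 * days), tolerance = 1e-9)
  # bkill = 0: ER has no effect
  gp0 <- growth_params(b0 = 0.02, bkill = 0, gamma = 1)
  tv0 <- simulate_tumor(gp0, flat_zero, days, v0 = 200)
  expect_equal(tv0$volume_mm3, 200 * 10^(0.02 * days), tolerance = 1e-12)
})

test_that("growth-rate fit is exact on model data and applies the 15 mm3 floor", {
  days <- c(0, 3, 7, 10, 14, 17, 21)
  fit <- fit_growth_rate(data.frame(day = days, volume_mm3 = 100 * 10^(0.02 * days)))
  expect_equal(fit$b, 0.02, tolerance = 1e-12)
  expect_equal(fit$a, 2, tolerance = 1e-12)

  # a 10 mm3 observation participates as 15 mm3
  vols <- c(100, 40, 10)
  d <- c(0, 7, 14)
  fit_floor <- fit_growth_rate(data.frame(day = d, volume_mm3 = vols))
  manual <- ols_oracle(d, log10(c(100, 40, 15)))
  expect_equal(fit_floor$b, manual$b, tolerance = 1e-12)
  unfloored <- ols_oracle(d, log10(vols))
  expect_false(isTRUE(all.equal(fit_floor$b, unfloored$b)))

  expect_error(fit_growth_rate(data.frame(day = c(0, 7), volume_mm3 = c(1, 2))),
               "3 measurement days")
})

test_that("noisy growth-rate fits agree with an independent regression oracle", {
  set.seed(3)
  days <- c(0, 3, 7, 10, 14, 17, 21, 24)
  for (i in 1:20) {
    v <- 150 * 10^(0.025 * days) * exp(rnorm(8, 0, sqrt(log(1 + 0.15^2))))
    fit <- fit_growth_rate(data.frame(day = days, volume_mm3 = v))
    oracle <- ols_oracle(days, log10(pmax(v, 15)))
    expect_equal(fit$b, oracle$b, tolerance = 1e-9)
    expect_true(fit$b >= oracle$ci_b[1] && fit$b <= oracle$ci_b[2])
  }
})

test_that("growth fit on zero-noise simulated vehicle recovers the true rate", {
  des <- study_design(list(vehicle = NULL), n_per_arm = 3, duration_days = 21)
  truth <- default_truth()
  b <- simulate_study(des, truth, noise_model(0, 0, 0, 0, seed = 5))
  for (a in unique(b$volumes$animal)) {
    fit <- fit_growth_rate(b$volumes[b$volumes$animal == a, ])
    expect_equal(fit$b, truth$growth$b0, tolerance = 1e-9)
  }
})

test_that("percent TV change implements the baseline-normalized formula", {
  mk <- function(v_end) data.frame(day = c(0, 21), volume_mm3 = c(200, v_end))
  expect_equal(percent_tv_change(mk(200)), 0)
  expect_equal(percent_tv_change(mk(300)), 50)
  expect_equal(percent_tv_change(mk(100)), -50)
  # invariance to rescaling all volumes
  d <- data.frame(day = c(0, 7, 21), volume_mm3 = c(180, 240, 410))
  d2 <- d; d2$volume_mm3 <- d$volume_mm3 * 3.7
  expect_equal(percent_tv_change(d), percent_tv_change(d2), tolerance = 1e-12)
})

test_that("TGI follows the geometric-mean change convention", {
  ctrl <- volume_table("vehicle", c(1.8, 2.0, 2.2))
  # control versus itself: 0%
  self <- tgi(ctrl, ctrl)
  expect_equal(self$tgi, 0, tolerance = 1e-12)
  # static treated arm: 100%
  static <- volume_table("tx", c(1, 1, 1))
  expect_equal(tgi(static, ctrl)$tgi, 100, tolerance = 1e-12)
  # GM_C = 2, GM_T = 1.5 -> 50%
  t15 <- volume_table("tx", c(1.5, 1.5, 1.5))
  c20 <- volume_table("vehicle", c(2, 2, 2))
  expect_equal(tgi(t15, c20)$tgi, 50, tolerance = 1e-12)
  # regression beyond stasis exceeds 100% and is reported unclipped
  reg <- volume_table("tx", c(0.5, 0.5, 0.5))
  expect_gt(tgi(reg, c20)$tgi, 100)
  # non-growing control is flagged undefined
  shrink <- volume_table("vehicle", c(0.8, 0.9, 0.95))
  res <- tgi(static, shrink)
  expect_false(res$defined)
  expect_true(is.na(res$tgi))
})

test_that("TGI is invariant to rescaling all volumes by a constant", {
  set.seed(11)
  tr <- volume_table("tx", exp(rnorm(6, 0.1, 0.2)))
  ct <- volume_table("vehicle", exp(rnorm(6, 0.7, 0.2)))
  r1 <- tgi(tr, ct)
  tr2 <- tr; tr2$volume_mm3 <- tr$volume_mm3 * 5.3
  ct2 <- ct; ct2$volume_mm3 <- ct$volume_mm3 * 5.3
  r2 <- tgi(tr2, ct2)
  expect_equal(r1$tgi, r2$tgi, tolerance = 1e-12)
})

test_that("endpoint handling carries forward only within the window", {
  ctrl <- volume_table("vehicle", c(2, 2, 2), end_day = 21)
  tr <- volume_table("tx", c(1.2, 1.3), end_day = 21)
  # one animal stops at day 17 (within 7 days of end): carried forward
  early <- data.frame(animal = "tx_99", arm = "tx", day = c(0, 17),
                      volume_mm3 = c(200, 260))
  res <- tgi(rbind(tr, early), ctrl)
  expect_equal(length(res$pct_change_treated), 3)
  # an animal last seen on day 10 (> 7 days before end) is excluded
  very_early <- data.frame(animal = "tx_98", arm = "tx", day = c(0, 10),
                           volume_mm3 = c(200, 220))
  expect_message(res2 <- tgi(rbind(tr, very_early), ctrl), "excluded")
  expect_equal(length(res2$pct_change_treated), 2)
})

test_that("the one-tailed Welch test matches an independently coded formula", {
  ctrl <- volume_table("vehicle", exp(c(1.0, 1.1, 0.9, 1.05)))
  tr <- volume_table("tx", exp(c(0.0, 0.1, -0.05, 0.08)))
  res <- compare_to_vehicle(tr, ctrl)
  oracle <- welch_oracle(c(0.0, 0.1, -0.05, 0.08), c(1.0, 1.1, 0.9, 1.05))
  expect_equal(res$p, oracle$p_less, tolerance = 1e-9)
  expect_equal(res$statistic, oracle$t, tolerance = 1e-9)
  expect_equal(res$df, oracle$df, tolerance = 1e-9)

  # identical groups: exact symmetric null
  same <- volume_table("tx", c(1.2, 1.5, 1.8))
  same2 <- same; same2$arm <- "vehicle"
  expect_equal(compare_to_vehicle(same, same2)$p, 0.5)

  one <- volume_table("tx", 1.5)
  expect_error(compare_to_vehicle(one, ctrl), "2 animals")
})

test_that("simulated TGI is monotone nondecreasing in dose", {
  des <- four_dose_design(n_per_arm = 6)
  truth <- default_truth()
  b <- simulate_study(des, truth, noise_model(0, 0, 0, 0, seed = 2))
  veh <- b$volumes[b$volumes$arm == "vehicle", ]
  tgis <- vapply(c("d1", "d3", "d10", "d30"), function(a) {
    tgi(b$volumes[b$volumes$arm == a, ], veh)$tgi
  }, 0)
  expect_true(all(diff(tgis) >= -1e-9))
})
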