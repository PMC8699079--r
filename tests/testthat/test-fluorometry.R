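test_that("percent reduction maps anchors to 0 and 100 and is affine-invariant", {
  expect_equal(percent_reduction(200, 200, 1000), 0)
  expect_equal(percent_reduction(1000, 200, 1000), 100)
  expect_equal(percent_reduction(600, 200, 1000), 50)
  # gain/offset on all three signals cancels
  withr::with_seed(51, {
    for (i in 1:20) {
      x0 <- runif(1, 100, 300); x100 <- runif(1, 600, 1200)
      x <- runif(1, x0, x100)
      g <- runif(1, 0.5, 3); o <- runif(1, -50, 50)
      expect_equal(percent_reduction(g * x + o, g * x0 + o, g * x100 + o),
                   percent_reduction(x, x0, x100))
    }
  })
  expect_error(percent_reduction(5, 3, 3), "degenerate")
  expect_warning(out <- percent_reduction(50, 200, 1000), "clamping")
  expect_equal(out, 0)
})

test_that("standard curves interpolate exactly and round-trip", {
  cur <- fit_standard_curve(c(0, 100), c(5, 205))
  expect_equal(cur$slope, 2)
  expect_equal(cur$intercept, 5)
  expect_equal(cur$r2, 1)
  expect_equal(apply_standard_curve(105, cur), 50)
  # round trip on every curve point
  withr::with_seed(52, {
    q <- c(0, 50, 100, 200, 400)
    s <- 3 + 1.7 * q + rnorm(5, 0, 2)
    cur <- fit_standard_curve(q, s)
    fitted_sig <- cur$intercept + cur$slope * q
    expect_equal(apply_standard_curve(fitted_sig, cur), q, tolerance = 1e-12)
  })
  expect_error(fit_standard_curve(c(1, 1), c(2, 3)), "singular")
  expect_warning(fit_standard_curve(c(0, 1, 2), c(0, 5, 1)), "r2")
})

test_that("TMRM calibration inverts the ratio-to-mV line", {
  cal <- fit_standard_curve(c(100, 200), c(1.5, 1.0))  # mV -> ratio
  expect_equal(tmrm_to_mv(1.5, cal)$delta_psi_mV, 100)
  expect_equal(tmrm_to_mv(1.25, cal)$delta_psi_mV, 150)  # midpoint
  expect_warning(tmrm_to_mv(2.0, cal), "extrapolating")
  flat <- fit_standard_curve(c(100, 200), c(1, 1))
  expect_error(tmrm_to_mv(1, flat), "non-monotone|zero slope")
})

test_that("TMRM generator round-trips membrane potential within 2 mV", {
  cfg <- synth_config()
  tm <- gen_tmrm_trace(cfg, "cardiac", "control", seed = 53)
  cal <- fit_standard_curve(tm$calibration$mv, tm$calibration$ratio)
  ser <- tmrm_series(tm$trace, cal, tm$truth$demand_labels,
                     settle_s = cfg$tmrm$settle_s)
  expect_true(all(abs(ser$delta_psi_mV - tm$truth$mv_true) < 2))
  # noiseless generator recovers exactly
  cfg0 <- synth_config()
  cfg0$tmrm$noise_ratio <- 0
  tm0 <- gen_tmrm_trace(cfg0, "renal", "CKD", seed = 1)
  cal0 <- fit_standard_curve(tm0$calibration$mv, tm0$calibration$ratio)
  ser0 <- tmrm_series(tm0$trace, cal0, tm0$truth$demand_labels)
  expect_equal(ser0$delta_psi_mV, tm0$truth$mv_true, tolerance = 1e-8)
})

test_that("H2O2 rates convert signal slopes through the standard curve", {
  # slope 10 a.u./min with 2 a.u./pmol and 50 ug -> 100 pmol/min/mg
  t <- 0:120
  tr <- fluor_trace(t, 100 + (10 / 60) * t)
  cur <- fit_standard_curve(c(0, 100), c(5, 205))  # 2 a.u. per pmol
  expect_equal(h2o2_rate(tr, c(0, 120), cur, 50), 100, tolerance = 1e-10)
  # flat trace -> 0
  expect_equal(h2o2_rate(fluor_trace(t, rep(7, 121)), c(0, 120), cur, 50), 0)
})

test_that("seeded H2O2 generator recovers the configured rates within 3%", {
  cfg <- synth_config()
  hz <- gen_h2o2_trace(cfg, "renal", "control", seed = 54)
  cur <- fit_standard_curve(hz$curve_points$known_quantity,
                            hz$curve_points$signal)
  ser <- h2o2_series(hz$trace, cur, cfg$h2o2$protein_ug,
                     hz$truth$demand_labels, settle_s = cfg$h2o2$settle_s)
  expect_true(all(abs(ser$jh2o2 / hz$truth$jh2o2_true - 1) < 0.03))
})

test_that("electron leak is the rate ratio on a common time base", {
  expect_equal(electron_leak(0, 50), 0)
  expect_equal(electron_leak(1, 100, h2o2_time_base = "per_s"), 1)
  expect_equal(electron_leak(60, 100), 1)  # 60 pmol/min == 1 pmol/s
  # scale invariance: same unit change on both rates cancels
  withr::with_seed(55, {
    jh <- runif(4, 1, 50); jo <- runif(4, 100, 900); k <- runif(1, 0.1, 10)
    expect_equal(electron_leak(k * jh, k * jo), electron_leak(jh, jo))
    expect_equal(electron_leak(jh, jo, h2o2_time_base = "per_s"),
                 100 * jh / jo)
  })
  expect_error(electron_leak(1, 0), "positive")
})

test_that("redox series recovers generator truth", {
  cfg <- synth_config()
  rx <- gen_redox_trace(cfg, "skeletal", "CKD", seed = 56)
  rs <- redox_series(rx$trace, rx$truth$demand_labels,
                     settle_s = cfg$redox$settle_s)
  expect_equal(rs$pct_reduction, rx$truth$pct_true, tolerance = 0.02)
  # noiseless round trip is exact
  cfg0 <- synth_config()
  cfg0$redox$noise_au <- 0
  rx0 <- gen_redox_trace(cfg0, "renal", "control", seed = 1)
  rs0 <- redox_series(rx0$trace, rx0$truth$demand_labels)
  expect_equal(rs0$pct_reduction, rx0$truth$pct_true, tolerance = 1e-10)
})
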