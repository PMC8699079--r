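test_that("linear_rate recovers a globally linear trace exactly", {
  t <- seq(0, 300, by = 2)
  # 0.5 a.u./s production, gain 1 a.u./pmol, 5 ug protein
  tr <- kinetic_trace(t, 20 + 0.5 * t, protein_ug = 5, enzyme = "PDH")
  cur <- fit_standard_curve(c(0, 1000), c(2, 1002))
  res <- linear_rate(tr, cur)
  expect_equal(res$rate, 0.5 * 60 / 0.005, tolerance = 1e-9)  # 6000 pmol/min/mg
  expect_equal(res$r2, 1)
})

test_that("linear_rate picks the middle segment of a lag/linear/plateau trace", {
  t <- seq(0, 300, by = 2)
  # lag to 40 s, linear at 0.8 a.u./s to 220 s, then plateau
  ramp <- pmin(pmax(t - 40, 0), 180)
  tr <- kinetic_trace(t, 10 + 0.8 * ramp, protein_ug = 5)
  res <- linear_rate(tr, NULL)
  # a.u./min/mg with no curve: 0.8 * 60 / 0.005
  expect_equal(res$rate, 0.8 * 60 / 0.005, tolerance = 1e-9)
  expect_true(res$window[1] >= 40 - 2 && res$window[2] <= 222)
})

test_that("linear_rate errors when no window is linear enough", {
  withr::with_seed(61, {
    t <- seq(0, 300, by = 2)
    tr <- kinetic_trace(t, rnorm(length(t), 50, 30), protein_ug = 5)
    expect_error(linear_rate(tr, NULL), "no linear phase")
  })
  expect_error(
    linear_rate(kinetic_trace(0:5, 1:6 * 1.0, protein_ug = 5), NULL),
    "at least 10")
})

test_that("rate is offset-invariant and scales with signal gain", {
  t <- seq(0, 300, by = 2)
  ramp <- pmin(pmax(t - 40, 0), 180)
  base <- linear_rate(kinetic_trace(t, 10 + 0.8 * ramp, protein_ug = 5), NULL)
  off <- linear_rate(kinetic_trace(t, 510 + 0.8 * ramp, protein_ug = 5), NULL)
  gain <- linear_rate(kinetic_trace(t, 10 + 1.6 * ramp, protein_ug = 5), NULL)
  expect_equal(off$rate, base$rate, tolerance = 1e-9)
  expect_equal(gain$rate, 2 * base$rate, tolerance = 1e-9)
  # after curve conversion, a shared gain cancels
  cur1 <- fit_standard_curve(c(0, 1000), c(0, 1000))
  cur2 <- fit_standard_curve(c(0, 1000), c(0, 2000))
  r1 <- linear_rate(kinetic_trace(t, 10 + 0.8 * ramp, protein_ug = 5), cur1)
  r2 <- linear_rate(kinetic_trace(t, 10 + 1.6 * ramp, protein_ug = 5), cur2)
  expect_equal(r1$rate, r2$rate, tolerance = 1e-9)
})

test_that("ATP synthase assay reports NADH consumption 1:1 and needs a consumption trace", {
  t <- seq(0, 300, by = 2)
  ramp <- pmin(pmax(t - 40, 0), 180)
  # NADH consumed at 50 pmol/min per mg-equivalent signal:
  # 5 ug, gain 1 -> slope a.u./s = 50 * 0.005 / 60
  sl <- 50 * 0.005 / 60
  tr <- kinetic_trace(t, 100 - sl * ramp, direction = "consumption",
                      protein_ug = 5)
  cur <- fit_standard_curve(c(0, 1000), c(0, 1000))
  res <- atp_synthase_rate(tr, cur)
  expect_equal(res$rate, 50, tolerance = 1e-9)
  expect_equal(res$enzyme, "CV")
  # flat trace -> 0
  flat <- kinetic_trace(t, rep(100, length(t)), direction = "consumption",
                        protein_ug = 5)
  expect_equal(atp_synthase_rate(flat, cur)$rate, 0)
  prod <- kinetic_trace(t, 100 + sl * ramp, protein_ug = 5)
  expect_error(atp_synthase_rate(prod, cur), "consumption")
})

test_that("seeded noisy enzyme fixture recovers truth within 5%", {
  cfg <- synth_config()
  for (ez in c("PDH", "CIV", "HADHA", "CV")) {
    g <- gen_enzyme_trace(cfg, ez, "cardiac", "control", seed = 62)
    cur <- fit_standard_curve(g$curve_points$known_quantity,
                              g$curve_points$signal)
    res <- linear_rate(g$trace, cur)
    expect_lt(abs(res$rate / g$truth$rate_true - 1), 0.05)
    expect_gte(res$rate, 0)  # direction correction keeps activities positive
  }
})

test_that("activity group comparison matches the pooled-t oracle", {
  withr::with_seed(63, {
    x <- rnorm(6, 6000, 400); y <- rnorm(6, 3720, 400)
    g <- activity_group_compare(x, y)
    expect_equal(g$percent_change, 100 * (mean(x) - mean(y)) / mean(x))
    expect_equal(g$t, oracle_pooled_t(x, y), tolerance = 1e-12)
  })
  eq <- activity_group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$percent_change, 0)
})

test_that("plate reader import assembles traces from the plate map", {
  pf <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, 100, by = 10)
  plate <- rbind(
    data.frame(well = "A1", time_s = t, signal = 10 + 0.5 * t),
    data.frame(well = "A2", time_s = t, signal = 200 - 0.2 * t))
  map <- data.frame(well = c("A1", "A2"), enzyme = c("PDH", "HADHA"),
                    sample = c("s1", "s1"), group = c("control", "control"),
                    direction = c("production", "consumption"),
                    protein_ug = c(5, 5))
  write.csv(plate, pf, row.names = FALSE)
  write.csv(map, mf, row.names = FALSE)
  trs <- read_plate_traces(pf, mf)
  expect_named(trs, c("A1", "A2"))
  expect_equal(trs$A1$enzyme, "PDH")
  expect_equal(trs$A2$direction, "consumption")
  expect_equal(linear_rate(trs$A2, NULL)$rate, 0.2 * 60 / 0.005,
               tolerance = 1e-9)
})
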