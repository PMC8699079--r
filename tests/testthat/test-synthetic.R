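test_that("generators are deterministic under a fixed seed", {
  cfg <- synth_config()
  a <- gen_resp_trace(cfg, "cardiac", "control", seed = 91)
  b <- gen_resp_trace(cfg, "cardiac", "control", seed = 91)
  expect_identical(a, b)
  expect_identical(gen_reporter_matrix(cfg, "renal", seed = 91),
                   gen_reporter_matrix(cfg, "renal", seed = 91))
  expect_identical(gen_phenotypes(cfg, seed = 91),
                   gen_phenotypes(cfg, seed = 91))
  expect_identical(gen_redox_trace(cfg, "renal", "CKD", seed = 91),
                   gen_redox_trace(cfg, "renal", "CKD", seed = 91))
  # different seeds differ
  expect_false(identical(a, gen_resp_trace(cfg, "cardiac", "control", 92)))
})

test_that("noiseless respirometry round trip recovers the slope exactly", {
  cfg <- synth_config()
  cfg$resp$noise_uM <- 0
  cfg$animal_sdlog <- 0
  for (ti in c("skeletal", "cardiac", "renal")) {
    g <- gen_resp_trace(cfg, ti, "control", seed = 1)
    a <- analyze_resp_trace(cfg, g$trace)
    expect_equal(a$fit$slope, cfg$tissues[[ti]]$control_slope,
                 tolerance = 1e-9)
    expect_equal(a$jo2, g$truth$jo2_true, tolerance = 1e-9)
    expect_equal(a$fit$r2, 1, tolerance = 1e-9)
  }
  # CKD multiplier scales the recovered slope
  gk <- gen_resp_trace(cfg, "renal", "CKD", seed = 1)
  ak <- analyze_resp_trace(cfg, gk$trace)
  expect_equal(ak$fit$slope,
               cfg$tissues$renal$control_slope * cfg$tissues$renal$ckd_multiplier,
               tolerance = 1e-9)
})

test_that("per-trace conductance recovery has < 5% median error at default noise", {
  cfg <- synth_config()
  tissues <- rep(c("skeletal", "cardiac", "renal"), length.out = 200)
  groups <- rep(c("control", "CKD"), length.out = 200)
  relerr <- vapply(seq_len(200), function(i) {
    g <- gen_resp_trace(cfg, tissues[i], groups[i], seed = 900 + i)
    a <- analyze_resp_trace(cfg, g$trace)
    abs(a$fit$slope / g$truth$slope_true - 1)
  }, 0)
  expect_lt(median(relerr), 0.05)
})

test_that("cytochrome-c rule excludes exactly the damaged samples", {
  cfg <- synth_config()
  for (i in 1:80) {
    g <- gen_resp_trace(cfg, "skeletal", "control", seed = 2000 + i)
    dec <- cytc_exclusion(100, 100 + g$truth$cytc_response_pct,
                          threshold_pct = cfg$cytc$threshold_pct)
    expect_identical(dec$exclude, g$truth$damaged)
  }
})

test_that("noiseless reporter matrix recovers loading factors", {
  cfg <- synth_config()
  cfg$proteome$log2_sd <- 0
  cfg$proteome$da_n <- c(skeletal = 0, cardiac = 0, renal = 0)
  g <- gen_reporter_matrix(cfg, "cardiac", seed = 93)
  nm <- loading_normalize(g$matrix)
  expect_equal(unname(nm$loading_factors),
               unname(g$truth$loading_factors_norm), tolerance = 1e-6)
})

test_that("null proteome keeps the BH-significant fraction at bay", {
  cfg <- synth_config()
  cfg$proteome$da_n <- c(skeletal = 0, cardiac = 0, renal = 0)
  cfg$proteome$n_proteins <- 400
  fr <- vapply(1:10, function(i) {
    g <- gen_reporter_matrix(cfg, "skeletal", seed = 940 + i)
    da <- differential_abundance(log2_center(loading_normalize(g$matrix)))
    mean(da$p_adj < 0.05)
  }, 0)
  expect_lte(mean(fr), 0.05)
})

test_that("configured differential proteins rank at the top", {
  cfg <- synth_config()
  g <- gen_reporter_matrix(cfg, "renal", seed = 95)
  da <- differential_abundance(log2_center(loading_normalize(g$matrix)))
  k <- nrow(g$truth$da)
  top <- da$protein[order(da$p)][seq_len(2 * k)]
  expect_gte(mean(g$truth$da$protein %in% top), 0.90)
  # skeletal muscle is configured with no differential proteins
  g0 <- gen_reporter_matrix(cfg, "skeletal", seed = 95)
  expect_equal(nrow(g0$truth$da), 0)
})

test_that("phenotype generator matches the configured group summaries", {
  cfg <- synth_config()
  ph <- gen_phenotypes(cfg, seed = 96)
  expect_equal(nrow(ph), 14)
  bun_ckd <- ph$bun_mg_dl[ph$group == "CKD"]
  se <- 18.35 / sqrt(7)
  expect_lt(abs(mean(bun_ckd) - 105.3), 2 * se)
  # large-n means converge to the configured truth
  cfg_big <- synth_config()
  cfg_big$phenotypes$n_per_group <- 4000
  big <- gen_phenotypes(cfg_big, seed = 97)
  expect_equal(mean(big$body_g[big$group == "control"]), 32.9,
               tolerance = 0.01)
  expect_equal(sd(big$bun_mg_dl[big$group == "CKD"]), 18.35,
               tolerance = 0.05)
})

test_that("electron leak of generated series equals the elementwise ratio", {
  cfg <- synth_config()
  cfg$h2o2$noise_au <- 0
  cfg$h2o2$curve_noise_au <- 0
  cfg$resp$noise_uM <- 0
  cfg$animal_sdlog <- 0
  hz <- gen_h2o2_trace(cfg, "cardiac", "CKD", seed = 1)
  cur <- fit_standard_curve(hz$curve_points$known_quantity,
                            hz$curve_points$signal)
  jh <- h2o2_series(hz$trace, cur, cfg$h2o2$protein_ug,
                    hz$truth$demand_labels)$jh2o2
  g <- gen_resp_trace(cfg, "cardiac", "CKD", seed = 1)
  jo <- analyze_resp_trace(cfg, g$trace)$jo2
  expect_equal(electron_leak(jh, jo), 100 * (jh / 60) / jo,
               tolerance = 1e-9)
  expect_equal(jh, hz$truth$jh2o2_true, tolerance = 1e-9)
})
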