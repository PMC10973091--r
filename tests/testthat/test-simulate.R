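test_that("profile validation rejects bad parameters and canonicalizes taus", {
  expect_error(gt_profile("x", ec50_glu = -1, ec50_gly = 1), "positive")
  expect_error(gt_profile("x", ec50_glu = 1, ec50_gly = 1, po_max = 1.5), "po_max")
  expect_error(gt_profile("x", ec50_glu = 1, ec50_gly = 1, frac_fast = 1.2),
               "frac_fast")
  # swapped taus are exchanged and the fast fraction re-expressed
  p <- gt_profile("x", ec50_glu = 1, ec50_gly = 1,
                  tau_fast = 100, tau_slow = 30, frac_fast = 0.2)
  expect_equal(p$tau_fast, 30)
  expect_equal(p$tau_slow, 100)
  expect_equal(p$frac_fast, 0.8)
  expect_equal(profile_tau_weighted(p), 0.8 * 30 + 0.2 * 100)
})

test_that("sim_config enforces protocol invariants", {
  expect_error(sim_config(concentration_series = c(1, 2, 3)), "4 points")
  expect_error(sim_config(concentration_series = c(3, 2, 1, 0.5)),
               "increasing")
  expect_error(sim_config(voltage_steps = c(10, 20, 30)), "sign change")
})

test_that("concentration-response generation matches the Hill curve", {
  # half-maximal point, no noise
  expect_equal(hill_response(3.5, 3.5, 1), 50)
  # inhibitor at 1000 uM with IC50 19: 100/(1 + 1000/19)
  expect_equal(hill_response(1000, 19, 1, "inhibitor"), 100 / (1 + 1000 / 19),
               tolerance = 1e-12)
  expect_equal(hill_response(1000, 19, 1, "inhibitor"), 1.864, tolerance = 1e-3)

  p <- noise_off(gt_profile("x", ec50_glu = 3.5, ec50_gly = 1,
                            hill_glu = 1, tau_fast = 30, tau_slow = 90))
  d <- sim_concentration_response(p, sim_config(
    n_cells = 1, concentration_series = c(0.35, 3.5, 35, 350)), seed = 1)
  expect_equal(d$response_pct[2], 50)
  expect_equal(d$response_pct,
               hill_response(d$concentration_uM, 3.5, 1))
})

test_that("generators are bitwise-deterministic under a fixed seed", {
  wt <- wt2a()
  cfg <- sim_config(n_cells = 3)
  expect_identical(sim_concentration_response(wt, cfg, seed = 7),
                   sim_concentration_response(wt, cfg, seed = 7))
  expect_identical(sim_deactivation_traces(wt, cfg, seed = 7),
                   sim_deactivation_traces(wt, cfg, seed = 7))
  expect_identical(sim_mtsea_pairs(wt, 5, seed = 7),
                   sim_mtsea_pairs(wt, 5, seed = 7))
  expect_identical(sim_iv_families(wt, cfg, n_cells = 2, seed = 7),
                   sim_iv_families(wt, cfg, n_cells = 2, seed = 7))
  p1 <- sim_variant_panel(list(wt), cfg, seed = 3)
  p2 <- sim_variant_panel(list(wt), cfg, seed = 3)
  expect_identical(p1, p2)
  # and different seeds differ
  expect_false(identical(sim_mtsea_pairs(wt, 5, seed = 7),
                         sim_mtsea_pairs(wt, 5, seed = 8)))
})

test_that("deactivation traces reject undersampling and short durations", {
  wt <- wt2a()
  expect_error(
    sim_deactivation_trace(wt, sim_config(sample_interval = 50)),
    "Undersampled")
  expect_error(
    sim_deactivation_trace(wt, sim_config(trace_duration = 100)),
    "5x")
})

test_that("noise-free trace reproduces the biexponential shape exactly", {
  p <- noise_off(gt_profile("x", ec50_glu = 1, ec50_gly = 1,
                            tau_fast = 30, tau_slow = 100, frac_fast = 0.8,
                            peak_current = 120))
  cfg <- sim_config(t_app = 10, rise_time_10_90 = 5)
  tr <- sim_deactivation_trace(p, cfg)
  # decay samples follow the biexponential with the configured parameters
  t0 <- cfg$t_app
  dec <- tr$time_ms > t0
  td <- tr$time_ms[dec] - t0
  amp0 <- tr$current_pA[tr$time_ms == t0]
  expect_equal(tr$current_pA[dec],
               amp0 * (0.8 * exp(-td / 30) + 0.2 * exp(-td / 100)),
               tolerance = 1e-10)
  # pre-application baseline is flat zero without noise
  expect_true(all(tr$current_pA[tr$time_ms < 0] == 0))
})

test_that("MTSEA pair generation encodes Po through the potentiation fold", {
  p <- noise_off(gt_profile("x", ec50_glu = 1, ec50_gly = 1, po_max = 0.67))
  d <- sim_mtsea_pairs(p, 3, seed = 1)
  expect_equal(d$i_mtsea_nA / d$i_control_nA, rep(1, 3))
  p$po_max <- 0.24
  d <- sim_mtsea_pairs(p, 3, seed = 1)
  expect_equal(unique(round(d$i_mtsea_nA / d$i_control_nA, 6)),
               round(0.67 / 0.24, 6))
  p$po_max <- 0.033
  d <- sim_mtsea_pairs(p, 1, seed = 1)
  expect_equal(d$i_mtsea_nA / d$i_control_nA, 0.67 / 0.033)
  expect_true(all(d$i_control_nA > 0 & d$i_mtsea_nA > 0))
})

test_that("IV families reverse at the configured potential", {
  p <- noise_off(wt2a())
  na <- sim_iv_family(p, solution = "Na")
  ba <- sim_iv_family(p, solution = "Ba")
  expect_equal(na$current_nA[na$voltage_mV == 0], 0)
  expect_equal(as.numeric(estimate_reversal_potential(ba)), 12.1,
               tolerance = 1e-9)
})

test_that("absorbance ramps recover the generating slope", {
  d <- sim_absorbance_series(0.001, noise_sd = 0, seed = 1)
  expect_equal(unname(coef(lm(absorbance ~ time_min, d))[2]), 0.001,
               tolerance = 1e-12)
  # surface at half the WT rate, totals equal -> expression ratio 0.5
  p <- noise_off(gt_profile("v", ec50_glu = 1, ec50_gly = 1,
                            surface_ratio = 0.5))
  wt <- noise_off(gt_profile("w", ec50_glu = 1, ec50_gly = 1))
  r <- expression_ratio_from_plates(sim_expression_assay(p, seed = 1),
                                    sim_expression_assay(wt, seed = 2))
  expect_equal(r, 0.5, tolerance = 1e-9)
  # WT against itself is exactly 1
  r1 <- expression_ratio_from_plates(sim_expression_assay(wt, seed = 3),
                                     sim_expression_assay(wt, seed = 3))
  expect_equal(r1, 1)
})

test_that("the full panel composes every assay with consistent labels", {
  wt <- wt2a()
  panel <- sim_variant_panel(list(wt, preset_profile("lof_trafficking")),
                             sim_config(n_cells = 2), seed = 5)
  expect_named(panel, c("cr_series", "traces", "mtsea", "iv", "expression",
                        "t_app"))
  ids <- c("WT GluN1/2A", "LoF trafficking GluN1/2A-like")
  for (tbl in c("cr_series", "traces", "mtsea", "iv", "expression")) {
    expect_setequal(unique(panel[[tbl]]$construct_id), ids)
  }
  expect_setequal(unique(panel$cr_series$ligand),
                  c("glutamate", "glycine", "Mg"))
})
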