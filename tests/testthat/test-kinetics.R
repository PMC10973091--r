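biexp_trace <- function(frac_fast = 0.8, tau_fast = 30, tau_slow = 100,
                        peak = 100, dt = 1, t_app = 10, duration = 600,
                        noise_sd = 0, seed = 1) {
  p <- gt_profile("x", ec50_glu = 1, ec50_gly = 1, tau_fast = tau_fast,
                  tau_slow = tau_slow, frac_fast = frac_fast,
                  peak_current = peak, baseline_sd = noise_sd,
                  noise_cv = 0, cell_cv = 0)
  sim_deactivation_trace(p, sim_config(sample_interval = dt, t_app = t_app,
                                       trace_duration = duration),
                         seed = seed)
}

test_that("a pure single exponential is handled without split components", {
  tr <- biexp_trace(frac_fast = 1, tau_fast = 50, tau_slow = 50.0001,
                    duration = 300)
  f <- fit_deactivation(tr)
  expect_equal(f$status, "single_exponential")
  expect_equal(f$tau_weighted, 50, tolerance = 1e-3)
})

test_that("noiseless biexponential decay is recovered exactly", {
  tr <- biexp_trace(0.8, 30, 100)
  f <- fit_deactivation(tr)
  expect_equal(f$status, "ok")
  expect_equal(f$tau_fast, 30, tolerance = 1e-3)
  expect_equal(f$tau_slow, 100, tolerance = 1e-3)
  # weighted tau of the measured decay: amplitudes at the decay onset
  f_dec <- 0.8 * exp(-1 / 30) / (0.8 * exp(-1 / 30) + 0.2 * exp(-1 / 100))
  expect_equal(f$tau_weighted, f_dec * 30 + (1 - f_dec) * 100,
               tolerance = 1e-3)
  expect_equal(f$tau_weighted, 44, tolerance = 0.01)
})

test_that("weighted tau is the amplitude-weighted mean", {
  expect_equal(weighted_tau(1, 30, 1, 100), 65)
  expect_equal(weighted_tau(0.8, 30, 0.2, 100), 44)
  expect_equal(weighted_tau(5, 30, 0, 100), 30)
  expect_error(weighted_tau(0, 30, 0, 100), "zero")
})

test_that("weighted tau is a convex combination of the two taus", {
  set.seed(42)
  for (i in 1:200) {
    taus <- sort(stats::runif(2, 1, 2000))
    amps <- stats::runif(2, 0, 10)
    if (sum(amps) == 0) next
    tw <- weighted_tau(amps[1], taus[1], amps[2], taus[2])
    expect_gte(tw, taus[1])
    expect_lte(tw, taus[2])
  }
  # equals either tau at the amplitude extremes
  expect_equal(weighted_tau(0, 30, 2, 100), 100)
  expect_equal(weighted_tau(2, 30, 0, 100), 30)
})

test_that("biexponential model fits biexponential truth better than single", {
  tr <- biexp_trace(0.6, 20, 200, duration = 1200, noise_sd = 0.5, seed = 9)
  f <- fit_deactivation(tr)
  expect_equal(f$status, "ok")
  # refit forced single-exponential via a collapsed profile for comparison
  win <- attr(tr, "application_window")
  td <- tr$time_ms[tr$time_ms > win[2] + 0.5] - (win[2] + 1)
  id <- tr$current_pA[tr$time_ms > win[2] + 0.5]
  single <- minpack.lm::nlsLM(id ~ a * exp(-td / tau),
                              start = list(a = max(id), tau = 60))
  expect_lt(f$rss, sum(residuals(single)^2))
})

test_that("tiny peaks are reported as too small to measure", {
  tr <- biexp_trace(peak = 0.5, noise_sd = 1, seed = 2)
  f <- fit_deactivation(tr)
  expect_equal(f$status, "too_small_to_measure")
  expect_true(is.na(f$tau_weighted))
})

test_that("rise time uses linear interpolation of the 10/90 crossings", {
  # linear ramp 0 -> peak over 10 ms: 10-90 span is 8 ms
  tr <- tibble::tibble(time_ms = seq(-5, 30, 0.01),
                       current_pA = pmin(pmax(time_ms, 0), 10) * 10)
  expect_equal(as.numeric(rise_time_10_90(tr, c(0, 30))), 8,
               tolerance = 1e-6)
  # exponential onset tau = 5 ms: closed form 5 * log(9)
  tr2 <- tibble::tibble(time_ms = seq(-5, 60, 0.01))
  tr2$current_pA <- ifelse(tr2$time_ms < 0, 0, 100 * (1 - exp(-tr2$time_ms / 5)))
  expect_equal(as.numeric(rise_time_10_90(tr2, c(0, 60))), 5 * log(9),
               tolerance = 1e-3)
  expect_equal(as.numeric(rise_time_10_90(tr2, c(0, 60))), 10.99,
               tolerance = 1e-2)
  # flat trace has no identifiable peak
  tr3 <- tibble::tibble(time_ms = seq(-5, 30, 0.1), current_pA = 0)
  expect_error(rise_time_10_90(tr3, c(0, 30)), "peak")
})

test_that("desensitization extent measures the plateau deficit", {
  # flat plateau at peak: no desensitization
  tr <- tibble::tibble(time_ms = seq(-10, 1000, 1),
                       current_pA = ifelse(time_ms < 0, 0, 100))
  expect_equal(desensitization_extent(tr, c(0, 1000)), 0, tolerance = 1e-9)
  # plateau at 40% of peak
  tr2 <- tibble::tibble(time_ms = seq(-10, 1000, 1))
  tr2$current_pA <- ifelse(tr2$time_ms < 0, 0,
                           40 + 60 * exp(-pmax(tr2$time_ms, 0) / 50))
  expect_equal(desensitization_extent(tr2, c(0, 1000)), 0.6,
               tolerance = 0.01)
  # generator round-trip at configured plateau fraction
  p <- wt2a()
  tr3 <- sim_prolonged_trace(p, sim_config(), plateau_fraction = 0.5,
                             seed = 4)
  expect_equal(desensitization_extent(tr3), 0.5, tolerance = 0.05)
  expect_error(desensitization_extent(tr3, c(0, 5)), "too short")
})

test_that("charge transfer product multiplies peak and weighted tau", {
  expect_equal(charge_transfer_product(100, 44), 4400)
  expect_equal(charge_transfer_product(0, 44), 0)
  expect_equal(charge_transfer_product(153, 44), 6732)
  expect_error(charge_transfer_product(-1, 44), "non-negative")
})

test_that("panel summary averages per-cell fits (fit-then-average)", {
  wt <- wt2a()
  tr <- sim_deactivation_traces(wt, sim_config(n_cells = 6), seed = 21)
  res <- summarise_deactivation(tr)
  expect_equal(nrow(res$per_cell), 6)
  expect_equal(res$summary$n, 6)
  expect_equal(res$summary$tau_weighted_mean,
               mean(res$per_cell$tau_weighted), tolerance = 1e-12)
  expect_equal(res$summary$tau_weighted_mean, 44, tolerance = 0.25 * 44)
})
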