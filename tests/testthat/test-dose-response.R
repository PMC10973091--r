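noiseless_series <- function(ec50, n, conc = 10^seq(-2, 2, 0.5) * ec50,
                             mode = "agonist", minimum = 0) {
  tibble::tibble(concentration_uM = conc,
                 response_pct = hill_response(conc, ec50, n, mode, minimum))
}

test_that("noiseless agonist data are recovered exactly", {
  d <- noiseless_series(3.5, 1.2)
  f <- fit_hill(d)
  expect_equal(f$potency_uM, 3.5, tolerance = 1e-6)
  expect_equal(f$hill_n, 1.2, tolerance = 1e-6)
  expect_true(f$converged)
  expect_true(f$ci_low <= f$potency_uM && f$potency_uM <= f$ci_high)
})

test_that("noiseless inhibitor data are recovered with constrained minimum", {
  d <- noiseless_series(19, 1, mode = "inhibitor")
  f <- fit_inhibitor(d)
  expect_equal(f$potency_uM, 19, tolerance = 1e-5)
  expect_gte(f$minimum_pct, 0)
  # response at the IC50 itself is 50% by definition
  expect_equal(hill_response(19, 19, 1, "inhibitor"), 50)
  # non-zero plateau is picked up when present
  d2 <- noiseless_series(19, 1, mode = "inhibitor", minimum = 12)
  f2 <- fit_inhibitor(d2)
  expect_equal(f2$minimum_pct, 12, tolerance = 1e-4)
})

test_that("degenerate input with fewer than 4 concentrations errors", {
  d <- tibble::tibble(concentration_uM = c(1, 10), response_pct = c(10, 90))
  expect_error(fit_hill(d), "4 distinct")
  expect_error(fit_hill(dplyr::mutate(d, concentration_uM = c(-1, 10))),
               "positive")
})

test_that("fit agrees with a dense grid-search oracle on noiseless grids", {
  for (case in list(c(3.5, 1.3), c(0.08, 0.9), c(150, 2.1))) {
    d <- noiseless_series(case[1], case[2])
    f <- fit_hill(d, normalize = "none")
    oracle <- grid_search_hill(d$concentration_uM, d$response_pct)
    expect_equal(f$potency_uM, unname(oracle["ec50"]), tolerance = 5e-3)
    expect_equal(f$hill_n, unname(oracle["n"]), tolerance = 5e-3)
  }
})

test_that("rescaling concentrations by k shifts the potency by exactly k", {
  wt <- wt2a()
  d <- sim_concentration_response(wt, sim_config(n_cells = 4), seed = 11)
  f1 <- fit_hill(d)
  k <- 7.3
  f2 <- fit_hill(dplyr::mutate(d, concentration_uM = concentration_uM * k))
  expect_equal(f2$potency_uM / f1$potency_uM, k, tolerance = 1e-6)
  expect_equal(f2$hill_n, f1$hill_n, tolerance = 1e-6)
})

test_that("fitted curves are monotonic in concentration", {
  wt <- wt2a()
  d <- sim_concentration_response(wt, sim_config(n_cells = 6), seed = 3)
  f <- fit_hill(d)
  grid <- 10^seq(-3, 4, length.out = 100)
  pred <- hill_response(grid, f$potency_uM, f$hill_n)
  expect_true(all(diff(pred) > 0))
  dm <- sim_concentration_response(wt, sim_config(n_cells = 6),
                                   mode = "inhibitor", seed = 3)
  fm <- fit_inhibitor(dm)
  predm <- hill_response(grid, fm$potency_uM, fm$hill_n, "inhibitor",
                         fm$minimum_pct)
  expect_true(all(diff(predm) < 0))
})

test_that("potency far outside the sampled range raises a flag", {
  d <- noiseless_series(3.5, 1.1, conc = c(1000, 3000, 10000, 30000, 1e5))
  f <- fit_hill(d, normalize = "none")
  expect_true("potency_outside_range" %in% f$flags)
})

test_that("relative response ratios evaluate the fitted curves", {
  d1 <- noiseless_series(0.1, 1)
  d2 <- noiseless_series(1.2, 1)
  fv <- fit_hill(d1, normalize = "none")
  fw <- fit_hill(d2, normalize = "none")
  # (3/3.1)/(3/4.2) by hand
  expect_equal(relative_response_ratio(fv, fw, 3), (3 / 3.1) / (3 / 4.2),
               tolerance = 1e-4)
  expect_equal(relative_response_ratio(fv, fw, 3), 1.355, tolerance = 1e-3)
  # identical fits give 1 at any concentration
  expect_equal(relative_response_ratio(fw, fw, 0.01), 1)
  expect_equal(relative_response_ratio(fw, fw, 500), 1)
  # saturating concentrations drive the ratio to 1
  expect_equal(relative_response_ratio(fv, fw, 1e6), 1, tolerance = 1e-3)
  # inhibitor fits are rejected
  fm <- fit_inhibitor(noiseless_series(19, 1, mode = "inhibitor"))
  expect_error(relative_response_ratio(fm, fw, 3), "agonist")
})

test_that("percent inhibition follows the inhibition curve", {
  expect_equal(percent_inhibition_at(19, 1000), 100 - 100 / (1 + 1000 / 19))
  expect_equal(percent_inhibition_at(19, 1000), 98.1, tolerance = 1e-2)
  expect_equal(percent_inhibition_at(19, 0), 0)
  expect_equal(percent_inhibition_at(1000, 1000), 50)
  f <- fit_inhibitor(noiseless_series(19, 1, mode = "inhibitor"))
  expect_equal(percent_inhibition_at(f, 1000), 98.1, tolerance = 0.1)
})

test_that("confidence-interval non-overlap drives significance calls", {
  # overlapping intervals: not significant
  r <- ci_nonoverlap_significant(c(3.1, 4.8), c(3.4, 3.6))
  expect_false(r$significant)
  # disjoint and below: increased potency
  r <- ci_nonoverlap_significant(c(1.2, 1.4), c(3.4, 3.6))
  expect_true(r$significant)
  expect_equal(r$direction, "increased_potency")
  # disjoint and above: decreased potency
  r <- ci_nonoverlap_significant(c(8.0, 9.1), c(3.4, 3.6))
  expect_true(r$significant)
  expect_equal(r$direction, "decreased_potency")
  # identical intervals overlap
  expect_false(ci_nonoverlap_significant(c(3.4, 3.6), c(3.4, 3.6))$significant)
})

test_that("tidy/glance/autoplot methods work on hill fits", {
  f <- fit_hill(noiseless_series(3.5, 1.2))
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "ec50_uM"], 3.5, tolerance = 1e-5)
  g <- glance(f)
  expect_true(g$converged)
  expect_s3_class(autoplot(f), "ggplot")
})
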