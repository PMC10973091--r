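test_that("wild-type self-comparison yields unit charge transfer", {
  wt <- make_profile()
  expect_equal(as.numeric(synaptic_charge_transfer(wt, wt)), 1)
  expect_equal(as.numeric(nonsynaptic_charge_transfer(wt, wt)), 1)
})

test_that("synaptic charge transfer is the product of its six terms", {
  wt <- make_profile()
  v <- make_profile(tau_w = 88, po = 0.48, surface_ratio = 0.5)
  ct <- synaptic_charge_transfer(v, wt)
  terms <- attr(ct, "terms")
  expect_equal(as.numeric(ct), prod(terms))
  expect_equal(unname(terms["tau"]), 2)
  expect_equal(unname(terms["po"]), 2)
  expect_equal(unname(terms["surface"]), 0.5)
  # worked product: tau 2, po 2, surf 0.5, r_gly 1.2, r_glu 1.05, mg 1
  manual <- 2 * 2 * 0.5 * 1.2 * 1.05 * 1.0
  expect_equal(manual, 2.52)
})

test_that("non-synaptic transfer drops tau and uses ambient glutamate", {
  wt <- make_profile(hill_glu = 1)
  v <- make_profile(ec50_glu = 0.3, hill_glu = 1, tau_w = NA)
  ct <- nonsynaptic_charge_transfer(v, wt)
  # (0.1/0.4)/(0.1/3.6) = 9.0 by direct evaluation at 0.1 uM
  expect_equal(unname(attr(ct, "terms")["r_glu"]), 9.0)
  expect_false("tau" %in% names(attr(ct, "terms")))
  # tau missing still yields a value for the non-synaptic composite
  expect_false(is.na(ct))
  # ... but makes the synaptic composite undefined
  expect_true(is.na(synaptic_charge_transfer(v, wt)))
})

test_that("both composites are multiplicative in every single ratio", {
  wt <- make_profile()
  v <- make_profile(ec50_glu = 1.1, ec50_gly = 0.6, ic50_mg = 40,
                    po = 0.4, tau_w = 100, surface_ratio = 0.7)
  base_syn <- as.numeric(synaptic_charge_transfer(v, wt))
  base_non <- as.numeric(nonsynaptic_charge_transfer(v, wt))
  k <- 3.3
  for (col in c("po", "tau_w", "surface_ratio")) {
    v2 <- v
    v2[[col]] <- v2[[col]] * k
    expect_equal(as.numeric(synaptic_charge_transfer(v2, wt)), base_syn * k,
                 tolerance = 1e-12)
    if (col != "tau_w") {
      expect_equal(as.numeric(nonsynaptic_charge_transfer(v2, wt)),
                   base_non * k, tolerance = 1e-12)
    }
  }
})

test_that("assay grading maps folds and significance to votes", {
  # unit fold: no vote regardless of significance
  g <- grade_assay_change(1.0, "po", TRUE)
  expect_equal(g$direction, "none")
  # reduced Mg sensitivity (IC50 fold 4.9, significant) supports GoF
  g2 <- grade_assay_change(93 / 19, "mg_ic50", TRUE)
  expect_equal(g2$direction, "GoF")
  expect_equal(g2$confidence, "H")
  # severe surface loss supports LoF with high confidence
  g3 <- grade_assay_change(0.055, "surface", TRUE)
  expect_equal(g3$direction, "LoF")
  expect_equal(g3$confidence, "H")
  # sub-2-fold significant change is moderate confidence
  g4 <- grade_assay_change(1.5, "tau_w", TRUE)
  expect_equal(g4$confidence, "M")
  # non-significant changes contribute nothing
  g5 <- grade_assay_change(10, "po", FALSE)
  expect_equal(g5$direction, "none")
  expect_error(grade_assay_change(2, "unknown_assay", TRUE), "Unknown assay")
})

test_that("classification applies the decision rules in order", {
  none <- grade_assay_change(1, "po", TRUE)
  gof2 <- dplyr::bind_rows(grade_assay_change(3, "po", TRUE),
                           grade_assay_change(2.2, "tau_w", TRUE))
  lof2 <- dplyr::bind_rows(grade_assay_change(0.3, "po", TRUE),
                           grade_assay_change(0.1, "surface", TRUE))
  mixed <- dplyr::bind_rows(grade_assay_change(3, "po", TRUE),
                            grade_assay_change(0.3, "surface", TRUE))
  # all quiet: no change
  expect_equal(classify_call(none, 1.0, 1.0), "no change")
  # agreeing votes classify directly
  expect_equal(classify_call(gof2, 5, 4), "GoF")
  expect_equal(classify_call(lof2, 0.012, 0.020), "LoF")
  # conflicting votes rescued by a suprathreshold composite
  expect_equal(classify_call(mixed, 3.0, 1.0), "Possible GoF")
  expect_equal(classify_call(mixed, 1.0, 0.2), "Possible LoF")
  # both composites suprathreshold in conflict: Indeterminant
  expect_equal(classify_call(mixed, 3.0, 0.2), "Indeterminant")
  # unmeasurable tau with all else done: starred Indeterminant
  expect_equal(classify_call(gof2, NA, 8, tau_status = "too_small_to_measure"),
               "Indeterminant*")
  # conflicting votes, subthreshold composites: no change
  expect_equal(classify_call(mixed, 1.2, 0.8), "no change")
})

test_that("classification is total and order-stable over random inputs", {
  set.seed(7)
  assays <- c("glu_potency", "gly_potency", "mg_ic50", "po", "tau_w",
              "surface")
  valid <- c("GoF", "LoF", "Possible GoF", "Possible LoF", "Indeterminant",
             "Indeterminant*", "no change")
  for (i in 1:100) {
    folds <- exp(stats::rnorm(6, 0, 1.2))
    sig <- stats::runif(6) < 0.7
    votes <- purrr::map2_dfr(folds, seq_along(assays),
                             ~ grade_assay_change(.x, assays[.y], sig[.y]))
    ct <- exp(stats::rnorm(2, 0, 1.5))
    call1 <- classify_call(votes, ct[1], ct[2])
    # permuting assay order must not change the call
    perm <- votes[sample(nrow(votes)), ]
    call2 <- classify_call(perm, ct[1], ct[2])
    expect_true(call1 %in% valid)
    expect_identical(call1, call2)
  }
})

test_that("profile-level classification produces a coherent ledger row", {
  wt <- make_profile("WT", glu_sig = FALSE, gly_sig = FALSE, mg_sig = FALSE,
                     po_sig = FALSE, tau_sig = FALSE, surf_sig = FALSE)
  v <- make_profile("VAR", ec50_glu = 0.35, ec50_gly = 0.12, po = 0.48,
                    tau_w = 260, glu_sig = TRUE, gly_sig = TRUE,
                    mg_sig = FALSE, po_sig = TRUE, tau_sig = TRUE,
                    surf_sig = FALSE)
  row <- classify_profile(v, wt)
  expect_equal(row$call, "GoF")
  expect_equal(row$fold_glu_potency, 10)
  expect_equal(row$fold_tau_w, 260 / 44, tolerance = 1e-12)
  expect_gt(row$ct_syn, 2.5)
  expect_equal(row$n_gof_high, 4)
  # the wild type classifies as no change against itself
  expect_equal(classify_profile(wt, wt)$call, "no change")
})

test_that("suprathreshold counting ignores missing entries", {
  expect_equal(count_suprathreshold(c(3, 2.4, NA, 2.6, 0.1)), 2)
  expect_equal(count_suprathreshold(numeric(0)), 0)
})

test_that("two-state occupancy relation links Po and EC50", {
  expect_equal(ec50_po_relation(0, 10), 10)
  expect_equal(ec50_po_relation(0.5, 10), 5)
  po <- seq(0, 0.95, 0.05)
  expect_true(all(diff(ec50_po_relation(po, 3)) < 0))
  expect_error(ec50_po_relation(1, 3), "po")
})
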