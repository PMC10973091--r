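#' Ground-truth functional profile of an NMDA-receptor construct
#'
#' Bundles the generating-side parameters the synthetic assay simulators
#' draw from: agonist potencies and Hill slopes, Mg2+ block, maximal open
#' probability, biexponential deactivation kinetics, peak current density,
#' relative surface expression, proton sensitivity, and the Ba2+-induced
#' reversal-potential shift.  Downstream estimators should recover these
#' values from simulated data, which is the basis of every round-trip test
#' in the package.
#'
#' Deactivation time constants are canonicalized so that
#' `tau_fast <= tau_slow`; when the two inputs arrive swapped they are
#' exchanged and `frac_fast` is re-expressed as the amplitude fraction of
#' the (new) fast component.
#'
#' @param construct_id Text label, e.g. `"WT GluN1/2A"`.
#' @param ec50_glu,ec50_gly Agonist EC50s in uM (strictly positive).
#' @param hill_glu,hill_gly Hill slopes for the two agonists.
#' @param ic50_mg Mg2+ IC50 in uM at a fixed holding potential.
#' @param hill_mg Hill slope of the Mg2+ inhibition curve.
#' @param po_max Maximal channel open probability, in (0, 1].
#' @param tau_fast,tau_slow Deactivation time constants in ms.
#' @param frac_fast Amplitude fraction of the fast component, in \[0, 1\].
#' @param peak_current Peak current density in pA/pF.
#' @param surface_ratio Surface/total expression relative to wild type.
#' @param ph_ratio Current at pH 6.8 divided by current at pH 7.6, as a
#'   fraction.
#' @param vrev_shift_ba Ba2+-induced reversal-potential shift in mV.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (lognormal, unit-mean) noise applied to steady-state responses.
#' @param baseline_sd Additive Gaussian noise SD on current traces, pA.
#' @param cell_cv Coefficient of variation of the per-cell lognormal
#'   jitter applied to kinetic parameters and peak currents, emulating
#'   cell-to-cell biological variability.
#'
#' @return An object of class `gt_profile` (a named list).
#' @export
#' @examples
#' wt <- gt_profile("WT GluN1/2A", ec50_glu = 3.5, ec50_gly = 1.2,
#'                  tau_fast = 33, tau_slow = 88)
#' wt$ec50_glu
gt_profile <- function(construct_id,
                       ec50_glu, ec50_gly,
                       hill_glu = 1.3, hill_gly = 1.2,
                       ic50_mg = 19, hill_mg = 1.0,
                       po_max = 0.24,
                       tau_fast = 33, tau_slow = 88, frac_fast = 0.8,
                       peak_current = 150,
                       surface_ratio = 1.0,
                       ph_ratio = 0.43,
                       vrev_shift_ba = 12.1,
                       noise_cv = 0.10,
                       baseline_sd = 2,
                       cell_cv = 0.25) {
  if (!is.character(construct_id) || length(construct_id) != 1) {
    abort("`construct_id` must be a single string.")
  }
  for (nm in c("ec50_glu", "ec50_gly", "ic50_mg", "hill_glu", "hill_gly",
               "hill_mg", "tau_fast", "tau_slow", "peak_current")) {
    assert_number(get(nm), nm, positive = TRUE)
  }
  assert_number(po_max, "po_max", lower = 1e-12, upper = 1)
  assert_number(frac_fast, "frac_fast", lower = 0, upper = 1)
  assert_number(surface_ratio, "surface_ratio", lower = 0)
  assert_number(ph_ratio, "ph_ratio", lower = 0)
  assert_number(vrev_shift_ba, "vrev_shift_ba")
  assert_number(noise_cv, "noise_cv", lower = 0)
  assert_number(baseline_sd, "baseline_sd", lower = 0)
  assert_number(cell_cv, "cell_cv", lower = 0)

  if (tau_fast > tau_slow) {
    tmp <- tau_fast
    tau_fast <- tau_slow
    tau_slow <- tmp
    frac_fast <- 1 - frac_fast
  }

  structure(
    list(construct_id = construct_id,
         ec50_glu = ec50_glu, ec50_gly = ec50_gly,
         hill_glu = hill_glu, hill_gly = hill_gly,
         ic50_mg = ic50_mg, hill_mg = hill_mg,
         po_max = po_max,
         tau_fast = tau_fast, tau_slow = tau_slow, frac_fast = frac_fast,
         peak_current = peak_current,
         surface_ratio = surface_ratio,
         ph_ratio = ph_ratio,
         vrev_shift_ba = vrev_shift_ba,
         noise_cv = noise_cv, baseline_sd = baseline_sd, cell_cv = cell_cv),
    class = "gt_profile"
  )
}

#' @export
print.gt_profile <- function(x, ...) {
  cat("<gt_profile>", x$construct_id, "\n")
  cat(sprintf("  glu EC50 %.3g uM (N %.2f) | gly EC50 %.3g uM (N %.2f) | Mg IC50 %.3g uM\n",
              x$ec50_glu, x$hill_glu, x$ec50_gly, x$hill_gly, x$ic50_mg))
  cat(sprintf("  Po %.3g | tau %.3g/%.3g ms (frac_fast %.2f, tau_w %.3g ms)\n",
              x$po_max, x$tau_fast, x$tau_slow, x$frac_fast,
              profile_tau_weighted(x)))
  cat(sprintf("  peak %.3g pA/pF | surface %.3g | pH ratio %.2f | dVrev(Ba) %.1f mV\n",
              x$peak_current, x$surface_ratio, x$ph_ratio, x$vrev_shift_ba))
  invisible(x)
}

#' Amplitude-weighted deactivation time constant implied by a profile
#'
#' @param profile A [gt_profile()].
#' @return Weighted tau in ms.
#' @export
profile_tau_weighted <- function(profile) {
  stopifnot(inherits(profile, "gt_profile"))
  profile$frac_fast * profile$tau_fast + (1 - profile$frac_fast) * profile$tau_slow
}

#' Switch off every noise source of a profile
#'
#' Convenience for exact round-trip tests: returns a copy of the profile
#' with response noise, trace baseline noise, and per-cell jitter all zero.
#'
#' @param profile A [gt_profile()].
#' @return A `gt_profile` with `noise_cv = baseline_sd = cell_cv = 0`.
#' @export
noise_off <- function(profile) {
  stopifnot(inherits(profile, "gt_profile"))
  profile$noise_cv <- 0
  profile$baseline_sd <- 0
  profile$cell_cv <- 0
  profile
}

#' Built-in ground-truth presets
#'
#' Presets mirror the published summary values for the wild-type
#' GluN1/GluN2A and GluN1/GluN2B diheteromers plus a small set of
#' illustrative variant profiles (a strong gain-of-function, a strong
#' loss-of-function, and a trafficking-deficient variant).  Noise levels
#' are calibrated so that simulated panels at the published sample sizes
#' reproduce the magnitude of the published standard errors (see the
#' methods vignette).
#'
#' @param name One of `preset_names()`.
#' @return A [gt_profile()].
#' @export
#' @examples
#' preset_profile("wt_glun1_2a")
preset_profile <- function(name) {
  presets <- list(
    # WT GluN1/GluN2A: glu EC50 3.5 uM, gly 1.2 uM, Mg IC50 19 uM,
    # Po 0.24, tau_w 44 ms (0.8*33 + 0.2*88), peak 153 pA/pF.
    wt_glun1_2a = gt_profile(
      "WT GluN1/2A",
      ec50_glu = 3.5, ec50_gly = 1.2, hill_glu = 1.3, hill_gly = 1.2,
      ic50_mg = 19, hill_mg = 1.0, po_max = 0.24,
      tau_fast = 33, tau_slow = 88, frac_fast = 0.8,
      peak_current = 153, surface_ratio = 1.0, ph_ratio = 0.43,
      vrev_shift_ba = 12.1, noise_cv = 0.10, baseline_sd = 2,
      cell_cv = 0.30),
    # WT GluN1/GluN2B: slower deactivation (tau_w 524 ms), low Po 0.033.
    wt_glun1_2b = gt_profile(
      "WT GluN1/2B",
      ec50_glu = 1.2, ec50_gly = 0.39, hill_glu = 1.3, hill_gly = 1.2,
      ic50_mg = 22, hill_mg = 1.0, po_max = 0.033,
      tau_fast = 300, tau_slow = 1420, frac_fast = 0.8,
      peak_current = 55, surface_ratio = 1.0, ph_ratio = 0.16,
      vrev_shift_ba = 12.1, noise_cv = 0.10, baseline_sd = 1,
      cell_cv = 0.22),
    # Strong gain of function on the 2A background: large potency
    # increase, saturating Po, greatly slowed deactivation, reduced
    # surface expression.
    gof_glun2a = gt_profile(
      "GoF GluN1/2A-like",
      ec50_glu = 0.17, ec50_gly = 0.076, hill_glu = 1.3, hill_gly = 1.2,
      ic50_mg = 33, hill_mg = 1.0, po_max = 0.97,
      tau_fast = 900, tau_slow = 4990, frac_fast = 0.8,
      peak_current = 87, surface_ratio = 0.34, ph_ratio = 0.97,
      vrev_shift_ba = 12.1, noise_cv = 0.10, baseline_sd = 2,
      cell_cv = 0.30),
    # Strong loss of function on the 2B background: reduced potency,
    # near-zero open probability, accelerated deactivation.
    lof_glun2b = gt_profile(
      "LoF GluN1/2B-like",
      ec50_glu = 4.1, ec50_gly = 0.96, hill_glu = 1.3, hill_gly = 1.2,
      ic50_mg = 19, hill_mg = 1.0, po_max = 0.0067,
      tau_fast = 60, tau_slow = 280, frac_fast = 0.8,
      peak_current = 56, surface_ratio = 1.0, ph_ratio = 0.37,
      vrev_shift_ba = 12.1, noise_cv = 0.10, baseline_sd = 1,
      cell_cv = 0.22),
    # Trafficking-deficient loss of function: near-normal gating but
    # ~5% of wild-type surface expression.
    lof_trafficking = gt_profile(
      "LoF trafficking GluN1/2A-like",
      ec50_glu = 0.46, ec50_gly = 0.22, hill_glu = 1.3, hill_gly = 1.2,
      ic50_mg = 46, hill_mg = 1.0, po_max = 0.05,
      tau_fast = 150, tau_slow = 500, frac_fast = 0.69,
      peak_current = 31, surface_ratio = 0.055, ph_ratio = 0.39,
      vrev_shift_ba = 12.1, noise_cv = 0.10, baseline_sd = 2,
      cell_cv = 0.30)
  )
  if (!name %in% names(presets)) {
    abort(sprintf("Unknown preset '%s'. Available: %s.",
                  name, paste(names(presets), collapse = ", ")))
  }
  presets[[name]]
}

#' @rdname preset_profile
#' @export
preset_names <- function() {
  c("wt_glun1_2a", "wt_glun1_2b", "gof_glun2a", "lof_glun2b",
    "lof_trafficking")
}

#' Simulation protocol configuration
#'
#' Collects the acquisition-protocol settings shared by the simulators:
#' number of cells, the concentration series, the voltage-step protocol
#' (15 mV steps from -90 to +30 mV), trace sampling, and the agonist
#' application window.
#'
#' The default concentration series is half-log spaced and spans
#' 0.01x to 100x the relevant potency, so it is constructed per assay
#' when left `NULL`.
#'
#' @param n_cells Cells (or oocytes) per construct and assay.
#' @param concentration_series Optional numeric vector of concentrations
#'   in uM; must be strictly increasing with at least 4 points.
#' @param voltage_steps Holding potentials in mV for the current-voltage
#'   protocol; must bracket a reversal (contain both signs).
#' @param sample_interval Trace sampling interval, ms.
#' @param trace_duration Trace duration in ms after application end;
#'   `NULL` means 6x the slow deactivation time constant.
#' @param t_app End of the brief agonist application, ms.
#' @param t_baseline Pre-application baseline recorded before the
#'   agonist arrives, ms.
#' @param rise_time_10_90 Simulated 10-90% rise time of the onset, ms.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 12,
                       concentration_series = NULL,
                       voltage_steps = c(-90, -75, -60, -45, -30, -15, 0, 15, 30),
                       sample_interval = 1,
                       trace_duration = NULL,
                       t_app = 10,
                       t_baseline = 20,
                       rise_time_10_90 = 5) {
  assert_number(n_cells, "n_cells", positive = TRUE)
  if (!is.null(concentration_series)) {
    if (length(concentration_series) < 4) {
      abort("`concentration_series` needs at least 4 points.")
    }
    if (any(concentration_series <= 0) ||
        any(diff(concentration_series) <= 0)) {
      abort("`concentration_series` must be strictly positive and increasing.")
    }
  }
  if (min(voltage_steps) >= 0 || max(voltage_steps) <= 0) {
    abort("`voltage_steps` must cover a sign change of the driving force.")
  }
  assert_number(sample_interval, "sample_interval", positive = TRUE)
  if (!is.null(trace_duration)) {
    assert_number(trace_duration, "trace_duration", positive = TRUE)
  }
  assert_number(t_app, "t_app", positive = TRUE)
  assert_number(t_baseline, "t_baseline", lower = 0)
  assert_number(rise_time_10_90, "rise_time_10_90", positive = TRUE)
  structure(
    list(n_cells = as.integer(n_cells),
         concentration_series = concentration_series,
         voltage_steps = sort(voltage_steps),
         sample_interval = sample_interval,
         trace_duration = trace_duration,
         t_app = t_app,
         t_baseline = t_baseline,
         rise_time_10_90 = rise_time_10_90),
    class = "sim_config"
  )
}

# Half-log series spanning 0.01x-100x the given midpoint potency.
default_concentration_series <- function(potency) {
  10^seq(log10(potency) - 2, log10(potency) + 2, by = 0.5)
}
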