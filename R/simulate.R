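#' Hill-equation response
#'
#' The two operating modes of the Hill model used throughout the package:
#' agonist activation, `100 / (1 + (EC50/c)^N)`, and channel-block
#' inhibition, `(100 - minimum) / (1 + (c/IC50)^N) + minimum`, both in
#' percent of the fitted maximum.
#'
#' @param concentration Concentration(s), uM.
#' @param potency EC50 (agonist mode) or IC50 (inhibitor mode), uM.
#' @param hill Hill slope, > 0.
#' @param mode `"agonist"` or `"inhibitor"`.
#' @param minimum Residual response at saturating inhibitor, percent
#'   (inhibitor mode only).
#' @return Response in percent of maximum.
#' @export
#' @examples
#' hill_response(3.5, 3.5, 1)            # half-maximal: 50
#' hill_response(1000, 19, 1, "inhibitor")
hill_response <- function(concentration, potency, hill,
                          mode = c("agonist", "inhibitor"), minimum = 0) {
  mode <- match.arg(mode)
  assert_number(potency, "potency", positive = TRUE)
  assert_number(hill, "hill", positive = TRUE)
  if (mode == "agonist") {
    100 / (1 + (potency / concentration)^hill)
  } else {
    (100 - minimum) / (1 + (concentration / potency)^hill) + minimum
  }
}

#' Simulate concentration-response series
#'
#' Draws per-cell concentration-response curves from a ground-truth
#' profile: the noiseless Hill curve evaluated at the concentration
#' series, multiplied by unit-mean lognormal noise with coefficient of
#' variation `profile$noise_cv`.  Responses follow the
#' percent-of-fitted-maximum convention (0-100).
#'
#' @param profile A [gt_profile()].
#' @param config A [sim_config()]; its `concentration_series` defaults to
#'   a half-log series spanning 0.01x-100x the relevant potency.
#' @param mode `"agonist"` or `"inhibitor"` (inhibitor draws from the
#'   Mg2+ block parameters).
#' @param ligand For agonist mode, `"glutamate"` or `"glycine"`.
#' @param minimum Residual response at saturating inhibitor, percent.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A tibble with columns `cell_id`, `construct_id`, `ligand`,
#'   `concentration_uM`, `response_pct`.
#' @export
#' @examples
#' wt <- preset_profile("wt_glun1_2a")
#' sim_concentration_response(wt, sim_config(n_cells = 2), seed = 1)
sim_concentration_response <- function(profile,
                                       config = sim_config(),
                                       mode = c("agonist", "inhibitor"),
                                       ligand = c("glutamate", "glycine"),
                                       minimum = 0,
                                       seed = NULL) {
  stopifnot(inherits(profile, "gt_profile"), inherits(config, "sim_config"))
  mode <- match.arg(mode)
  if (mode == "agonist") {
    ligand <- match.arg(ligand)
    potency <- if (ligand == "glutamate") profile$ec50_glu else profile$ec50_gly
    hill <- if (ligand == "glutamate") profile$hill_glu else profile$hill_gly
  } else {
    ligand <- "Mg"
    potency <- profile$ic50_mg
    hill <- profile$hill_mg
  }
  conc <- config$concentration_series %||% default_concentration_series(potency)
  clean <- hill_response(conc, potency, hill, mode, minimum)
  with_sim_seed(seed, {
    purrr::map_dfr(seq_len(config$n_cells), function(cell) {
      tibble(
        cell_id = sprintf("%s_cell%02d", ligand, cell),
        construct_id = profile$construct_id,
        ligand = ligand,
        concentration_uM = conc,
        response_pct = clean * lognormal_noise(length(conc), profile$noise_cv)
      )
    })
  })
}

# Deterministic noiseless trace shape: exponential 10-90 onset during the
# application window, biexponential decay afterwards.  Time 0 is the start
# of the agonist application; negative times are pre-application baseline.
trace_shape <- function(time, peak, tau_fast, tau_slow, frac_fast,
                        t_app, tau_rise) {
  onset_at <- function(t) peak * (1 - exp(-t / tau_rise))
  amp0 <- onset_at(t_app)
  current <- numeric(length(time))
  rising <- time >= 0 & time <= t_app
  decaying <- time > t_app
  current[rising] <- onset_at(time[rising])
  td <- time[decaying] - t_app
  current[decaying] <- amp0 * (frac_fast * exp(-td / tau_fast) +
                                 (1 - frac_fast) * exp(-td / tau_slow))
  current
}

#' Simulate a deactivation current trace
#'
#' Generates a uniformly sampled current trace: flat pre-application
#' baseline, a single-exponential onset whose 10-90% rise time is set by
#' the protocol, and, after the brief application ends, a biexponential
#' decay with the profile's time constants and fast-amplitude fraction.
#' Additive Gaussian noise of SD `profile$baseline_sd` is applied to every
#' sample.
#'
#' @param profile A [gt_profile()].
#' @param config A [sim_config()]; `trace_duration = NULL` uses 6x the
#'   slow time constant.  The sampling interval must resolve the fast
#'   component (`sample_interval < tau_fast`).
#' @param seed Integer seed.
#' @param tau_fast,tau_slow,frac_fast,peak Optional per-cell overrides of
#'   the profile parameters.
#' @return A tibble with `time_ms` and `current_pA`, with the application
#'   window `(0, t_app)` stored in the `"application_window"` attribute.
#' @export
sim_deactivation_trace <- function(profile, config = sim_config(),
                                   seed = NULL,
                                   tau_fast = profile$tau_fast,
                                   tau_slow = profile$tau_slow,
                                   frac_fast = profile$frac_fast,
                                   peak = profile$peak_current) {
  stopifnot(inherits(profile, "gt_profile"), inherits(config, "sim_config"))
  duration <- config$trace_duration %||% (6 * tau_slow)
  if (duration < 5 * tau_slow) {
    abort("`trace_duration` must be at least 5x the slow time constant.")
  }
  if (config$sample_interval >= tau_fast) {
    abort("Undersampled trace: `sample_interval` must be smaller than `tau_fast`.")
  }
  tau_rise <- config$rise_time_10_90 / log(9)
  time <- seq(-config$t_baseline, config$t_app + duration,
              by = config$sample_interval)
  clean <- trace_shape(time, peak, tau_fast, tau_slow, frac_fast,
                       config$t_app, tau_rise)
  out <- with_sim_seed(seed, {
    tibble(time_ms = time,
           current_pA = clean + rnorm(length(time), sd = profile$baseline_sd))
  })
  attr(out, "application_window") <- c(0, config$t_app)
  out
}

#' Simulate a panel of deactivation traces with cell-to-cell variability
#'
#' Applies unit-mean lognormal jitter (CV `profile$cell_cv`) to the two
#' deactivation time constants and the peak current of each cell, then
#' simulates one trace per cell with [sim_deactivation_trace()].
#'
#' @inheritParams sim_deactivation_trace
#' @param n_cells Number of cells; defaults to the protocol setting.
#' @return A tibble with `cell_id`, `time_ms`, `current_pA`; the
#'   application window is stored as an attribute.
#' @export
sim_deactivation_traces <- function(profile, config = sim_config(),
                                    n_cells = config$n_cells, seed = NULL) {
  stopifnot(inherits(profile, "gt_profile"))
  with_sim_seed(seed, {
    out <- purrr::map_dfr(seq_len(n_cells), function(cell) {
      jitter <- lognormal_noise(3, profile$cell_cv)
      trace <- sim_deactivation_trace(
        profile, config, seed = NULL,
        tau_fast = profile$tau_fast * jitter[1],
        tau_slow = profile$tau_slow * jitter[2],
        peak = profile$peak_current * jitter[3])
      mutate(trace, cell_id = sprintf("cell%02d", cell), .before = 1)
    })
    attr(out, "application_window") <- c(0, config$t_app)
    out
  })
}

#' Simulate a prolonged-application (desensitizing) trace
#'
#' A long agonist application during which the current sags from its peak
#' to a steady-state plateau, emulating receptor desensitization; the
#' application window is stored as an attribute so that the steady-state
#' extractor can find the plateau.
#'
#' @inheritParams sim_deactivation_trace
#' @param plateau_fraction Steady-state current as a fraction of peak.
#' @param t_app_long Application duration, ms.
#' @param tau_desens Time constant of the sag, ms.
#' @return A tibble with `time_ms`, `current_pA`.
#' @export
sim_prolonged_trace <- function(profile, config = sim_config(),
                                plateau_fraction = 0.5,
                                t_app_long = 1500, tau_desens = 200,
                                seed = NULL) {
  stopifnot(inherits(profile, "gt_profile"))
  assert_number(plateau_fraction, "plateau_fraction", lower = 0, upper = 1)
  tau_rise <- config$rise_time_10_90 / log(9)
  time <- seq(-config$t_baseline, t_app_long + 500,
              by = config$sample_interval)
  peak <- profile$peak_current
  current <- numeric(length(time))
  applied <- time >= 0 & time <= t_app_long
  current[applied] <- peak * (1 - exp(-time[applied] / tau_rise)) *
    (plateau_fraction + (1 - plateau_fraction) * exp(-pmax(time[applied] - 5 * tau_rise, 0) / tau_desens))
  after <- time > t_app_long
  current[after] <- current[max(which(applied))] *
    exp(-(time[after] - t_app_long) / profile$tau_slow)
  out <- with_sim_seed(seed, {
    tibble(time_ms = time,
           current_pA = current + rnorm(length(time), sd = profile$baseline_sd))
  })
  attr(out, "application_window") <- c(0, t_app_long)
  out
}

#' Simulate paired control/MTSEA steady-state currents
#'
#' MTSEA modification of the engineered reporter cysteine locks channels
#' open, so the current ratio after/before MTSEA (the potentiation) equals
#' `gamma_ratio / po_max` in expectation, where `gamma_ratio` is the
#' single-channel conductance ratio of modified to unmodified channels.
#' Each current carries independent unit-mean lognormal assay noise.
#'
#' @param profile A [gt_profile()].
#' @param n_cells Number of control/MTSEA pairs.
#' @param seed Integer seed.
#' @param gamma_ratio Conductance ratio gamma_MTSEA / gamma_control.
#' @param cv Assay noise CV per current measurement.
#' @param i_base Mean control current, nA.
#' @return A tibble with `cell_id`, `i_control_nA`, `i_mtsea_nA`.
#' @export
#' @examples
#' sim_mtsea_pairs(noise_off(preset_profile("wt_glun1_2a")), 2, seed = 1)
sim_mtsea_pairs <- function(profile, n_cells = 12, seed = NULL,
                            gamma_ratio = 0.67, cv = 0.10, i_base = 1.0) {
  stopifnot(inherits(profile, "gt_profile"))
  assert_number(gamma_ratio, "gamma_ratio", lower = 1e-9, upper = 1)
  if (profile$noise_cv == 0 && profile$baseline_sd == 0 &&
      profile$cell_cv == 0) {
    cv <- 0  # honour a fully noise-free profile
  }
  potentiation <- gamma_ratio / profile$po_max
  with_sim_seed(seed, {
    tibble(
      cell_id = sprintf("cell%02d", seq_len(n_cells)),
      i_control_nA = i_base * lognormal_noise(n_cells, cv),
      i_mtsea_nA = i_base * potentiation * lognormal_noise(n_cells, cv)
    )
  })
}

#' Simulate an agonist-evoked current-voltage family
#'
#' Difference currents (agonist minus baseline) at the 15 mV step
#' protocol, modeled as an ohmic conductance times the driving force,
#' with the Ba2+ solution shifting the reversal potential by the
#' profile's `vrev_shift_ba`.  An optional quadratic curvature term bends
#' the I-V relation; additive Gaussian noise emulates recording noise.
#'
#' @param profile A [gt_profile()].
#' @param config A [sim_config()] supplying `voltage_steps`.
#' @param solution `"Na"` or `"Ba"`.
#' @param seed Integer seed.
#' @param conductance Chord conductance, nA/mV.
#' @param v_rev_na Reversal potential in the Na+ solution, mV.
#' @param current_noise_sd Additive noise SD on each difference current, nA.
#' @param curvature Quadratic curvature coefficient (1/mV); 0 = ohmic.
#' @param inward_scale Scale factor applied to the inward limb of the
#'   I-V relation (negative driving force); values < 1 emulate a
#'   selective suppression of inward current, as seen when divalent
#'   permeation is reduced.  The reversal potential is unaffected.
#' @return A tibble with `solution`, `voltage_mV`, `current_nA`.
#' @export
sim_iv_family <- function(profile, config = sim_config(),
                          solution = c("Na", "Ba"), seed = NULL,
                          conductance = 20, v_rev_na = 0,
                          current_noise_sd = 12, curvature = 0,
                          inward_scale = 1) {
  stopifnot(inherits(profile, "gt_profile"))
  solution <- match.arg(solution)
  v_rev <- if (solution == "Na") v_rev_na else v_rev_na + profile$vrev_shift_ba
  g <- conductance
  v <- config$voltage_steps
  drive <- v - v_rev
  clean <- g * drive * (1 + curvature * drive)
  clean[drive < 0] <- clean[drive < 0] * inward_scale
  if (profile$noise_cv == 0 && profile$baseline_sd == 0 &&
      profile$cell_cv == 0) {
    current_noise_sd <- 0
  }
  with_sim_seed(seed, {
    tibble(solution = solution, voltage_mV = v,
           current_nA = clean + rnorm(length(v), sd = current_noise_sd))
  })
}

#' Simulate paired Na+/Ba2+ current-voltage families for many cells
#'
#' @inheritParams sim_iv_family
#' @param n_cells Number of cells; each cell contributes one Na+ and one
#'   Ba2+ family recorded at the same step protocol.
#' @return A tibble with `cell_id`, `solution`, `voltage_mV`, `current_nA`.
#' @export
sim_iv_families <- function(profile, config = sim_config(),
                            n_cells = config$n_cells, seed = NULL, ...) {
  with_sim_seed(seed, {
    purrr::map_dfr(seq_len(n_cells), function(cell) {
      bind_rows(
        sim_iv_family(profile, config, "Na", seed = NULL, ...),
        sim_iv_family(profile, config, "Ba", seed = NULL, ...)
      ) |>
        mutate(cell_id = sprintf("cell%02d", cell), .before = 1)
    })
  })
}

#' Simulate a beta-lactamase reporter absorbance time series
#'
#' The reporter enzyme cleaves a chromogenic substrate at a constant
#' rate, so absorbance at 486 nm rises linearly over the 30 min read;
#' the slope of a linear fit is the expression readout.
#'
#' @param rate Absorbance increase per minute.
#' @param duration Total read time, min.
#' @param interval Read interval, min.
#' @param noise_sd Additive Gaussian noise SD per read.
#' @param baseline Absorbance at time zero.
#' @param seed Integer seed.
#' @return A tibble with `time_min` and `absorbance`.
#' @export
sim_absorbance_series <- function(rate, duration = 30, interval = 1,
                                  noise_sd = 5e-4, baseline = 0.05,
                                  seed = NULL) {
  assert_number(rate, "rate", lower = 0)
  assert_number(duration, "duration", positive = TRUE)
  time <- seq(0, duration, by = interval)
  with_sim_seed(seed, {
    tibble(time_min = time,
           absorbance = baseline + rate * time +
             rnorm(length(time), sd = noise_sd))
  })
}

#' Simulate a surface/total expression assay plate
#'
#' Generates absorbance time series for surface and total (lysed) wells
#' of a construct plus mock-transfected background wells.  The variant's
#' surface rate is the wild-type surface rate scaled by the profile's
#' ground-truth `surface_ratio`; total rates are shared.
#'
#' @param profile A [gt_profile()].
#' @param n_wells Wells per compartment.
#' @param seed Integer seed.
#' @param wt_surface_rate,total_rate,background_rate Absorbance slopes
#'   per minute for wild-type surface wells, total wells, and
#'   mock-transfected background wells.
#' @param noise_sd Per-read absorbance noise SD.
#' @return A tibble with `well_id`, `construct_id`, `compartment`
#'   (surface / total / background), `time_min`, `absorbance`.
#' @export
sim_expression_assay <- function(profile, n_wells = 3, seed = NULL,
                                 wt_surface_rate = 0.010,
                                 total_rate = 0.012,
                                 background_rate = 5e-4,
                                 noise_sd = 5e-4) {
  stopifnot(inherits(profile, "gt_profile"))
  if (profile$noise_cv == 0 && profile$baseline_sd == 0 &&
      profile$cell_cv == 0) {
    noise_sd <- 0
  }
  # every well carries the mock-transfection background on top of the
  # reporter signal; the analysis subtracts it back out
  rates <- c(surface = background_rate + wt_surface_rate * profile$surface_ratio,
             total = background_rate + total_rate,
             background = background_rate)
  with_sim_seed(seed, {
    purrr::imap_dfr(rates, function(rate, compartment) {
      purrr::map_dfr(seq_len(n_wells), function(w) {
        sim_absorbance_series(rate, noise_sd = noise_sd, seed = NULL) |>
          mutate(well_id = sprintf("%s_w%02d", compartment, w),
                 construct_id = profile$construct_id,
                 compartment = compartment, .before = 1)
      })
    })
  })
}

#' Simulate a complete per-variant assay panel
#'
#' Composes the five assay simulators for each profile in a panel:
#' glutamate, glycine, and Mg2+ concentration-response series,
#' deactivation traces, MTSEA pairs, Na+/Ba2+ current-voltage families,
#' and the expression plate.  Every construct in `profiles` gets its own
#' dataset; put the same-day wild-type reference in the panel so that
#' downstream fold-changes can be formed.
#'
#' @param profiles A list of [gt_profile()] objects (include the
#'   wild-type reference).
#' @param config A [sim_config()].
#' @param seed Integer seed; sub-seeds are derived per construct and
#'   assay so the panel is reproducible element-wise.
#' @return A named list of tibbles: `cr_series`, `traces`, `mtsea`,
#'   `iv`, `expression`.
#' @export
#' @examples
#' panel <- sim_variant_panel(list(preset_profile("wt_glun1_2a")),
#'                            sim_config(n_cells = 2), seed = 1)
#' names(panel)
sim_variant_panel <- function(profiles, config = sim_config(), seed = 1) {
  if (inherits(profiles, "gt_profile")) profiles <- list(profiles)
  stopifnot(all(purrr::map_lgl(profiles, inherits, "gt_profile")))
  seed <- as.integer(seed)
  out <- purrr::imap(profiles, function(p, i) {
    s <- (seed * 97L + as.integer(i) * 1009L) %% .Machine$integer.max
    list(
      cr_series = bind_rows(
        sim_concentration_response(p, config, "agonist", "glutamate", seed = s + 1L),
        sim_concentration_response(p, config, "agonist", "glycine", seed = s + 2L),
        sim_concentration_response(p, config, "inhibitor", seed = s + 3L)
      ),
      traces = sim_deactivation_traces(p, config, seed = s + 4L) |>
        mutate(construct_id = p$construct_id, .before = 1),
      mtsea = sim_mtsea_pairs(p, n_cells = config$n_cells, seed = s + 5L) |>
        mutate(construct_id = p$construct_id, .before = 1),
      iv = sim_iv_families(p, config, seed = s + 6L) |>
        mutate(construct_id = p$construct_id, .before = 1),
      expression = sim_expression_assay(p, seed = s + 7L)
    )
  })
  list(
    cr_series = purrr::map_dfr(out, "cr_series"),
    traces = purrr::map_dfr(out, "traces"),
    mtsea = purrr::map_dfr(out, "mtsea"),
    iv = purrr::map_dfr(out, "iv"),
    expression = purrr::map_dfr(out, "expression"),
    t_app = config$t_app
  )
}
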