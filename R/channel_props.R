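#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Maximal open probability from MTSEA potentiation
#'
#' Covalent MTSEA modification of the engineered reporter cysteine locks
#' channels open, so the maximal open probability is the single-channel
#' conductance ratio divided by the fold potentiation:
#' `Po = gamma_ratio * i_control / i_mtsea`.  A fully open-locked
#' receptor can at most drop to `gamma_ratio` times the control current,
#' so potentiation below the conductance ratio (a computed probability
#' above 1) means MTSEA failed to label and lock the channel; such cells
#' carry status `"no_potentiation"` and no probability is reported for
#' them.  Potentiation between `gamma_ratio` and 1 is valid and maps to
#' probabilities between `gamma_ratio` and 1.
#'
#' @param i_control Steady-state agonist-evoked current(s) before MTSEA,
#'   nA.
#' @param i_mtsea Steady-state current(s) during MTSEA co-application,
#'   nA; must be strictly positive.
#' @param gamma_ratio Single-channel conductance ratio of MTSEA-modified
#'   to control channels (default 0.67).
#' @return A tibble with `i_control`, `i_mtsea`, `potentiation`, `po`,
#'   `status`.
#' @export
#' @examples
#' open_probability(1, 2.792)$po   # ~0.24
open_probability <- function(i_control, i_mtsea, gamma_ratio = 0.67) {
  if (length(i_control) != length(i_mtsea)) {
    abort("`i_control` and `i_mtsea` must have the same length.")
  }
  if (any(i_mtsea <= 0)) abort("`i_mtsea` must be strictly positive.")
  if (any(i_control <= 0)) abort("`i_control` must be strictly positive.")
  assert_number(gamma_ratio, "gamma_ratio", lower = 1e-9, upper = 1)
  potentiation <- i_mtsea / i_control
  po <- gamma_ratio / potentiation
  status <- dplyr::if_else(po > 1, "no_potentiation", "ok")
  po[status == "no_potentiation"] <- NA_real_
  tibble(i_control = i_control, i_mtsea = i_mtsea,
         potentiation = potentiation, po = po, status = status)
}

#' Summarise open probability over a set of control/MTSEA pairs
#'
#' @param pairs A tibble with `i_control_nA` and `i_mtsea_nA` (as
#'   produced by [sim_mtsea_pairs()]).
#' @param gamma_ratio Conductance ratio passed to [open_probability()].
#' @return One-row tibble with `po_mean`, `po_sem`, `n`,
#'   `n_no_potentiation`.
#' @export
summarise_open_probability <- function(pairs, gamma_ratio = 0.67) {
  assert_columns(pairs, c("i_control_nA", "i_mtsea_nA"))
  res <- open_probability(pairs$i_control_nA, pairs$i_mtsea_nA, gamma_ratio)
  ok <- res$po[res$status != "no_potentiation"]
  tibble(po_mean = mean(ok, na.rm = TRUE),
         po_sem = sd(ok, na.rm = TRUE) / sqrt(sum(!is.na(ok))),
         n = sum(!is.na(ok)),
         n_no_potentiation = sum(res$status == "no_potentiation"))
}

#' Proton-sensitivity current ratio
#'
#' Percent of the pH 7.6 current remaining at pH 6.8; lower values mean
#' stronger tonic proton inhibition.
#'
#' @param i_ph68,i_ph76 Steady-state currents at the two pH values;
#'   both must be strictly positive.
#' @return Percent, `100 * i_ph68 / i_ph76`.
#' @export
#' @examples
#' ph_current_ratio(43, 100)
ph_current_ratio <- function(i_ph68, i_ph76) {
  if (any(i_ph76 <= 0)) abort("`i_ph76` must be strictly positive.")
  if (any(i_ph68 <= 0)) abort("`i_ph68` must be strictly positive.")
  100 * i_ph68 / i_ph76
}

#' Absorbance slope of reporter wells
#'
#' Ordinary least-squares slope of absorbance versus time, per well - the
#' enzymatic-rate readout of the beta-lactamase expression assay.
#'
#' @param data A tibble with `well_id`, `time_min`, `absorbance`.
#' @return A tibble with one row per well: `well_id`, `slope`
#'   (absorbance/min), and any other constant well columns retained.
#' @export
fit_absorbance_slopes <- function(data) {
  assert_columns(data, c("well_id", "time_min", "absorbance"))
  keep <- setdiff(names(data), c("time_min", "absorbance"))
  data |>
    group_by(across(dplyr::all_of(keep))) |>
    summarise(slope = unname(coef(lm(absorbance ~ time_min))[2]),
              .groups = "drop")
}

#' Surface/total expression ratio relative to wild type
#'
#' Mean background-corrected surface slope over mean total slope for the
#' variant, normalized by the same quantity for the same-day wild-type
#' plate; the wild-type self-ratio is 1 by construction.  Invariant to
#' any plate-wide multiplicative gain.
#'
#' @param surface,total Numeric slopes (absorbance/min) for the variant
#'   wells.
#' @param wt_surface,wt_total Slopes for the wild-type reference wells.
#' @param background Scalar background slope (mock-transfected wells),
#'   subtracted from every slope before ratioing.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' expression_ratio(0.005, 0.012, 0.010, 0.012)  # 0.5
expression_ratio <- function(surface, total, wt_surface, wt_total,
                             background = 0) {
  ms <- mean(surface) - background
  mt <- mean(total) - background
  ws <- mean(wt_surface) - background
  wtt <- mean(wt_total) - background
  if (mt <= 0 || wtt <= 0) abort("Total expression slope must be positive after background correction.")
  if (ws <= 0) abort("Wild-type surface slope must be positive after background correction.")
  (ms / mt) / (ws / wtt)
}

#' Expression ratio straight from raw plate data
#'
#' Convenience wrapper: fits per-well slopes with
#' [fit_absorbance_slopes()], uses `background` wells as the correction,
#' and forms the [expression_ratio()] of a variant plate against a
#' wild-type plate.
#'
#' @param variant_plate,wt_plate Tibbles as produced by
#'   [sim_expression_assay()] (columns `well_id`, `compartment`,
#'   `time_min`, `absorbance`).
#' @return Dimensionless surface/total ratio, variant relative to WT.
#' @export
expression_ratio_from_plates <- function(variant_plate, wt_plate) {
  s_of <- function(plate, comp) {
    sl <- fit_absorbance_slopes(filter(plate, .data$compartment == comp))
    sl$slope
  }
  bg_v <- mean(s_of(variant_plate, "background"))
  bg_w <- mean(s_of(wt_plate, "background"))
  expression_ratio(
    s_of(variant_plate, "surface") - bg_v,
    s_of(variant_plate, "total") - bg_v,
    s_of(wt_plate, "surface") - bg_w,
    s_of(wt_plate, "total") - bg_w)
}
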