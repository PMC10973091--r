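#' Reversal potential of an I-V family by local linear interpolation
#'
#' Finds the voltage at which the agonist-evoked difference current
#' crosses zero, interpolating linearly between the two adjacent voltage
#' steps that bracket the sign change.  When several crossings exist
#' (noisy or non-monotonic families) the one nearest 0 mV is returned
#' with a `"multiple_crossings"` flag attribute.  The estimate is
#' invariant to uniform scaling of all currents.
#'
#' @param family A data frame with `voltage_mV` and `current_nA` (one
#'   cell, one solution).
#' @return Reversal potential in mV.
#' @export
#' @examples
#' estimate_reversal_potential(
#'   tibble::tibble(voltage_mV = c(-15, 0), current_nA = c(-1, 1)))  # -7.5
estimate_reversal_potential <- function(family) {
  assert_columns(family, c("voltage_mV", "current_nA"))
  d <- arrange(as_tibble(family), .data$voltage_mV)
  v <- d$voltage_mV
  i <- d$current_nA
  sign_change <- which(i[-length(i)] * i[-1] <= 0 &
                         (i[-length(i)] != 0 | i[-1] != 0))
  exact_zero <- which(i == 0)
  crossings <- c(
    purrr::map_dbl(sign_change, function(k) {
      if (i[k] == i[k + 1]) return((v[k] + v[k + 1]) / 2)
      v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
    }),
    v[exact_zero])
  crossings <- unique(crossings)
  if (length(crossings) == 0) {
    abort("Reversal not bracketed: currents do not change sign.")
  }
  out <- crossings[which.min(abs(crossings))]
  if (length(crossings) > 1) attr(out, "flag") <- "multiple_crossings"
  out
}

#' Ba2+-induced reversal-potential shift of one cell
#'
#' @param family_na,family_ba I-V families recorded in the Na+ and Ba2+
#'   solutions from the same cell.
#' @return Shift `V_rev(Ba) - V_rev(Na)` in mV.
#' @export
delta_vrev <- function(family_na, family_ba) {
  as.numeric(estimate_reversal_potential(family_ba)) -
    as.numeric(estimate_reversal_potential(family_na))
}

#' Screen a variant's Ba2+ reversal-potential shift against wild type
#'
#' The screen statistic is `ddv_rev = dv_rev(variant) - dv_rev(WT)`;
#' shifts beyond the +/- 3.4 mV threshold (the 99% confidence half-width
#' of the wild-type shift) are called as increased or decreased divalent
#' permeability.
#'
#' @param variant_shift,wt_shift Ba2+-induced reversal shifts, mV.
#' @param threshold Decision threshold, mV.
#' @return A one-row tibble: `dv_rev_variant`, `dv_rev_wt`, `ddv_rev`,
#'   `call` (`"increased"`, `"decreased"`, `"no_change"`).
#' @export
#' @examples
#' ddv_rev_screen(8.0, 12.1)$call  # "decreased"
ddv_rev_screen <- function(variant_shift, wt_shift, threshold = 3.4) {
  assert_number(threshold, "threshold", positive = TRUE)
  ddv <- variant_shift - wt_shift
  call <- dplyr::case_when(
    ddv > threshold ~ "increased",
    ddv < -threshold ~ "decreased",
    TRUE ~ "no_change"
  )
  tibble(dv_rev_variant = variant_shift, dv_rev_wt = wt_shift,
         ddv_rev = ddv, call = call)
}

#' Rectification ratio of an I-V family
#'
#' Ratio of the current at a hyperpolarized step to the current at a
#' depolarized step (default -75 mV over +30 mV); a suppressed inward
#' divalent current shows up as a reduced magnitude of this ratio in the
#' Ba2+ solution relative to Na+.
#'
#' @param family A data frame with `voltage_mV`, `current_nA`.
#' @param v_neg,v_pos The two voltages, mV; both must be present in the
#'   family.
#' @return Dimensionless ratio `I(v_neg) / I(v_pos)` (negative for an
#'   ohmic family reversing between the two steps).
#' @export
iv_current_ratio <- function(family, v_neg = -75, v_pos = 30) {
  assert_columns(family, c("voltage_mV", "current_nA"))
  pick <- function(v) {
    row <- family$current_nA[family$voltage_mV == v]
    if (length(row) == 0) abort(sprintf("Voltage %g mV not in family.", v))
    mean(row)
  }
  i_neg <- pick(v_neg)
  i_pos <- pick(v_pos)
  if (abs(i_pos) < 1e-9) abort("Current at the depolarized step is ~0; ratio undefined.")
  i_neg / i_pos
}

#' Compare Ba2+/Na+ rectification between a variant and wild type
#'
#' Forms `|I(-75)/I(+30)|` in Ba2+ relative to Na+ for the variant and
#' for wild type; a variant whose Ba2+/Na+ ratio-of-ratios falls below
#' `1 - tol` of the wild-type value is flagged `"reduced"` (consistent
#' with reduced divalent permeability), above `1 + tol` `"increased"`.
#'
#' @param variant_na,variant_ba,wt_na,wt_ba I-V families.
#' @param tol Relative tolerance around unity.
#' @return One-row tibble with the four ratios, the ratio-of-ratios fold,
#'   and `flag`.
#' @export
compare_current_ratios <- function(variant_na, variant_ba, wt_na, wt_ba,
                                   tol = 0.15) {
  rv_na <- iv_current_ratio(variant_na)
  rv_ba <- iv_current_ratio(variant_ba)
  rw_na <- iv_current_ratio(wt_na)
  rw_ba <- iv_current_ratio(wt_ba)
  fold <- (abs(rv_ba) / abs(rv_na)) / (abs(rw_ba) / abs(rw_na))
  flag <- dplyr::case_when(
    fold < 1 - tol ~ "reduced",
    fold > 1 + tol ~ "increased",
    TRUE ~ "no_change"
  )
  tibble(ratio_na_variant = rv_na, ratio_ba_variant = rv_ba,
         ratio_na_wt = rw_na, ratio_ba_wt = rw_ba,
         ba_na_fold = fold, flag = flag)
}

#' 99% confidence half-width from a standard error
#'
#' Normal-approximation half-width `z(0.995) * sem`; with the wild-type
#' reversal-shift SEM of 1.3 mV this reproduces the +/- 3.4 mV screening
#' threshold.
#'
#' @param sem Standard error of the mean, mV.
#' @param n Sample size (carried for the record; the normal quantile
#'   does not use it).
#' @return Half-width in mV.
#' @export
#' @examples
#' ci99_halfwidth(1.3)   # ~3.35
ci99_halfwidth <- function(sem, n = NULL) {
  if (any(sem < 0)) abort("`sem` must be non-negative.")
  qnorm(0.995) * sem
}

#' Run the permeability screen on simulated or recorded I-V data
#'
#' Estimates each cell's Na+ and Ba2+ reversal potentials, averages the
#' per-cell Ba2+-induced shifts, and screens the variant mean shift
#' against the wild-type mean shift.
#'
#' @param iv A tibble with `cell_id`, `solution` (`"Na"`/`"Ba"`),
#'   `voltage_mV`, `current_nA` for one construct.
#' @return One-row tibble: `dv_rev_mean`, `dv_rev_sem`, `n`.
#' @export
summarise_dv_rev <- function(iv) {
  assert_columns(iv, c("cell_id", "solution", "voltage_mV", "current_nA"))
  shifts <- iv |>
    group_by(.data$cell_id) |>
    dplyr::group_map(function(d, key) {
      tibble(cell_id = key$cell_id,
             dv_rev = delta_vrev(filter(d, .data$solution == "Na"),
                                 filter(d, .data$solution == "Ba")))
    }) |>
    bind_rows()
  tibble(dv_rev_mean = mean(shifts$dv_rev),
         dv_rev_sem = sd(shifts$dv_rev) / sqrt(nrow(shifts)),
         n = nrow(shifts))
}
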