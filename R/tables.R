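#' Published per-variant assay summaries for GRIN M3-helix variants
#'
#' Packaged transcriptions of the published per-variant summary tables
#' for the 48 missense variants in the M3 transmembrane helix of GluN1,
#' GluN2A and GluN2B. `grin_m3_pharmacology()` carries agonist EC50s
#' with 95% confidence intervals, Mg2+ IC50s, proton-sensitivity current
#' ratios and surface/total expression ratios; `grin_m3_biophysics()`
#' carries open probability, weighted deactivation tau, peak current
#' density, and the synaptic/non-synaptic charge-transfer folds.
#' Wild-type reference rows are included (`subunit == "WT"`); the
#' `wt_block` column of the biophysics table links each variant to its
#' pooled same-day wild-type control set.  Censored Mg2+ IC50s
#' (reported only as "> 1000 uM") are stored as 1000 with
#' `mg_censored = TRUE`; unmeasurable entries (responses too small) are
#' `NA` with a `tau_status` note.  One four-digit pair of
#' charge-transfer folds is typographically ambiguous in the source and
#' is transcribed as 4772/5502; both readings are far suprathreshold, so
#' no count or call depends on the choice.
#'
#' @return A tibble.
#' @export
#' @examples
#' nrow(grin_m3_pharmacology())
grin_m3_pharmacology <- function() {
  readr::read_csv(
    system.file("extdata", "grin_m3_pharmacology.csv", package = "grinfun"),
    show_col_types = FALSE)
}

#' @rdname grin_m3_pharmacology
#' @export
grin_m3_biophysics <- function() {
  readr::read_csv(
    system.file("extdata", "grin_m3_biophysics.csv", package = "grinfun"),
    show_col_types = FALSE)
}

#' Merged per-variant profile table with wild-type reference columns
#'
#' Joins the pharmacology and biophysics tables on construct and attaches
#' the matched wild-type reference values (`wt_glu_ec50`, `wt_gly_ec50`,
#' `wt_mg_ic50`, `wt_po`, `wt_tau_w`) so fold changes can be formed
#' row-wise; wild-type rows themselves are dropped.
#'
#' @return A tibble with one row per variant-background combination.
#' @export
grin_m3_profiles <- function() {
  pharm <- grin_m3_pharmacology()
  bio <- grin_m3_biophysics()
  wt_pharm <- pharm |>
    filter(.data$subunit == "WT") |>
    dplyr::distinct(.data$background, .keep_all = TRUE) |>
    select("background", wt_glu_ec50 = "glu_ec50", wt_gly_ec50 = "gly_ec50",
           wt_mg_ic50 = "mg_ic50")
  wt_bio <- bio |>
    filter(.data$subunit == "WT") |>
    select("wt_block", wt_po = "po", wt_tau_w = "tau_w")
  bio |>
    filter(.data$subunit != "WT") |>
    left_join(wt_bio, by = "wt_block") |>
    left_join(select(pharm, -"subunit", -"background"), by = "construct") |>
    left_join(wt_pharm, by = "background")
}
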