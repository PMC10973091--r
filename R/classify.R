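#' Reference conditions and thresholds for charge-transfer scoring and
#' classification
#'
#' All constants of the composite scoring are surfaced here: the assumed
#' extracellular glycine (3 uM), synaptic glutamate (1 mM) and ambient
#' non-synaptic glutamate (0.1 uM) concentrations, the 1 mM Mg2+ block
#' evaluation point, the single-channel conductance ratio for the
#' open-probability assay, the suprathreshold charge-transfer bounds
#' (> 2.5-fold or < 0.4-fold), the +/- 3.4 mV permeability threshold,
#' and the confidence-grading fold cutoff.
#'
#' @param conc_gly_uM,conc_glu_syn_uM,conc_glu_nonsyn_uM,conc_mg_uM
#'   Reference concentrations, uM.
#' @param gamma_ratio MTSEA/control conductance ratio.
#' @param ct_high,ct_low Suprathreshold charge-transfer fold bounds.
#' @param ddv_threshold_mV Permeability screen threshold, mV.
#' @param high_conf_fold Fold change at or beyond which a significant
#'   assay change is graded high confidence (below it: moderate).
#' @return A named list of class `profile_config`.
#' @export
profile_config <- function(conc_gly_uM = 3,
                           conc_glu_syn_uM = 1000,
                           conc_glu_nonsyn_uM = 0.1,
                           conc_mg_uM = 1000,
                           gamma_ratio = 0.67,
                           ct_high = 2.5,
                           ct_low = 0.4,
                           ddv_threshold_mV = 3.4,
                           high_conf_fold = 2) {
  cfg <- as.list(environment())
  for (nm in names(cfg)) assert_number(cfg[[nm]], nm, positive = TRUE)
  structure(cfg, class = "profile_config")
}

# required numeric columns of a one-row assay profile
profile_cols <- c("ec50_glu", "hill_glu", "ec50_gly", "hill_gly",
                  "ic50_mg", "hill_mg", "po", "tau_w", "surface_ratio")

ratio_term <- function(variant, wt, col) {
  v <- variant[[col]]
  w <- wt[[col]]
  if (is.null(v) || is.null(w) || is.na(v) || is.na(w)) NA_real_ else v / w
}

mg_inhibition_term <- function(profile, config) {
  # prefer a directly measured percent inhibition at 1 mM when present
  direct <- profile[["mg_inhibition_pct"]]
  if (!is.null(direct) && !is.na(direct)) return(direct)
  if (is.null(profile[["ic50_mg"]]) || is.na(profile[["ic50_mg"]])) {
    return(NA_real_)
  }
  hill <- profile[["hill_mg"]]
  if (is.null(hill) || is.na(hill)) hill <- 1
  percent_inhibition_at(profile[["ic50_mg"]], config$conc_mg_uM, hill = hill)
}

charge_transfer_terms <- function(variant, wt, config, synaptic = TRUE) {
  variant <- as.list(variant)
  wt <- as.list(wt)
  terms <- c(
    po = ratio_term(variant, wt, "po"),
    surface = ratio_term(variant, wt, "surface_ratio"),
    r_gly = response_ratio_at(variant$ec50_gly, variant$hill_gly,
                              wt$ec50_gly, wt$hill_gly, config$conc_gly_uM),
    r_glu = response_ratio_at(variant$ec50_glu, variant$hill_glu,
                              wt$ec50_glu, wt$hill_glu,
                              if (synaptic) config$conc_glu_syn_uM else config$conc_glu_nonsyn_uM),
    mg = mg_inhibition_term(variant, config) / mg_inhibition_term(wt, config)
  )
  if (synaptic) terms <- c(tau = ratio_term(variant, wt, "tau_w"), terms)
  terms
}

#' Relative fold-change in synaptic charge transfer
#'
#' Multiplicative composite of the six assay ratios for a brief synaptic
#' glutamate transient: deactivation tau, open probability, surface
#' expression, the relative responses to 3 uM glycine and 1 mM
#' glutamate, and the 1 mM Mg2+ inhibition ratio.  A variant whose
#' deactivation could not be measured (response too small) yields `NA`,
#' which downstream classification turns into the starred Indeterminant
#' category.
#'
#' @param variant,wt One-row data frames (or named lists) with columns
#'   `ec50_glu`, `hill_glu`, `ec50_gly`, `hill_gly`, `ic50_mg`,
#'   `hill_mg`, `po`, `tau_w`, `surface_ratio`; an optional
#'   `mg_inhibition_pct` overrides the IC50-derived Mg term.
#' @param config A [profile_config()].
#' @return The fold change (dimensionless) with the individual terms in
#'   the `"terms"` attribute.
#' @export
#' @examples
#' wt <- list(ec50_glu = 3.5, hill_glu = 1, ec50_gly = 1.2, hill_gly = 1,
#'            ic50_mg = 19, hill_mg = 1, po = 0.24, tau_w = 44,
#'            surface_ratio = 1)
#' synaptic_charge_transfer(wt, wt)  # 1
synaptic_charge_transfer <- function(variant, wt, config = profile_config()) {
  terms <- charge_transfer_terms(variant, wt, config, synaptic = TRUE)
  out <- prod(terms)
  attr(out, "terms") <- terms
  out
}

#' Relative fold-change in non-synaptic charge transfer
#'
#' As [synaptic_charge_transfer()] but with the time-dependence removed
#' (no tau term) and the glutamate response evaluated at the ambient
#' non-synaptic concentration of 0.1 uM.
#'
#' @inheritParams synaptic_charge_transfer
#' @return The fold change with a `"terms"` attribute.
#' @export
nonsynaptic_charge_transfer <- function(variant, wt,
                                        config = profile_config()) {
  terms <- charge_transfer_terms(variant, wt, config, synaptic = FALSE)
  out <- prod(terms)
  attr(out, "terms") <- terms
  out
}

# display-convention folds for the classification ledger: potency as WT/variant
# EC50 so that > 1 always reads as gain-of-function support
assay_display_folds <- function(variant, wt, config) {
  c(glu_potency = wt$ec50_glu / variant$ec50_glu,
    gly_potency = wt$ec50_gly / variant$ec50_gly,
    mg_ic50 = variant$ic50_mg / wt$ic50_mg,
    po = variant$po / wt$po,
    tau_w = variant$tau_w / wt$tau_w,
    surface = variant$surface_ratio / wt$surface_ratio)
}

#' Grade one assay's fold change into a directional confidence vote
#'
#' Folds follow the ledger display convention (> 1 supports gain of
#' function for every assay: increased potency, reduced Mg2+ block,
#' higher open probability, slower deactivation, more surface protein).
#' Significant changes are graded high confidence at or beyond the
#' configured fold cutoff and moderate below it; non-significant or
#' unit folds contribute no vote.
#'
#' @param fold Display-convention fold change.
#' @param assay One of `"glu_potency"`, `"gly_potency"`, `"mg_ic50"`,
#'   `"po"`, `"tau_w"`, `"surface"`.
#' @param significant Logical significance flag for the change.
#' @param config A [profile_config()].
#' @return One-row tibble: `assay`, `fold`, `direction` (`"GoF"`,
#'   `"LoF"`, `"none"`), `confidence` (`"H"`, `"M"`, `"none"`).
#' @export
#' @examples
#' grade_assay_change(4.9, "mg_ic50", TRUE)
grade_assay_change <- function(fold, assay, significant,
                               config = profile_config()) {
  known <- c("glu_potency", "gly_potency", "mg_ic50", "po", "tau_w",
             "surface")
  if (!assay %in% known) {
    abort(sprintf("Unknown assay key '%s'.", assay))
  }
  if (is.na(fold) || is.na(significant) || !significant || fold == 1) {
    return(tibble(assay = assay, fold = fold, direction = "none",
                  confidence = "none"))
  }
  direction <- if (fold > 1) "GoF" else "LoF"
  magnitude <- max(fold, 1 / fold)
  confidence <- if (magnitude >= config$high_conf_fold) "H" else "M"
  tibble(assay = assay, fold = fold, direction = direction,
         confidence = confidence)
}

#' Final classification call from votes and charge-transfer folds
#'
#' Applies the decision procedure in order: (1) variants whose
#' deactivation was unmeasurable because currents were too small - but
#' with all other assays completed - are `"Indeterminant*"`; (2) when all
#' directional votes agree the call is `"GoF"` or `"LoF"`; (3) when votes
#' conflict or none reach significance, both charge-transfer folds being
#' suprathreshold in opposite directions gives `"Indeterminant"`,
#' otherwise a suprathreshold fold rescues the variant to
#' `"Possible GoF"` (> 2.5) or `"Possible LoF"` (< 0.4); (4) anything
#' else is `"no change"`.  Every input reaches a call.
#'
#' @param votes A tibble of [grade_assay_change()] rows.
#' @param ct_syn,ct_nonsyn Charge-transfer folds (NA allowed).
#' @param tau_status `"measured"`, `"too_small_to_measure"`, or
#'   `"not_available"`.
#' @param all_other_assays_done Logical; required for the starred
#'   Indeterminant category.
#' @param config A [profile_config()].
#' @return A single classification string.
#' @export
classify_call <- function(votes, ct_syn, ct_nonsyn,
                          tau_status = "measured",
                          all_other_assays_done = TRUE,
                          config = profile_config()) {
  if (identical(tau_status, "too_small_to_measure") && all_other_assays_done) {
    return("Indeterminant*")
  }
  dirs <- unique(votes$direction[votes$direction != "none"])
  if (length(dirs) == 1) {
    return(dirs)
  }
  supra <- function(x) !is.na(x) && (x > config$ct_high || x < config$ct_low)
  up <- function(x) !is.na(x) && x > config$ct_high
  down <- function(x) !is.na(x) && x < config$ct_low
  if (supra(ct_syn) && supra(ct_nonsyn) &&
      ((up(ct_syn) && down(ct_nonsyn)) || (down(ct_syn) && up(ct_nonsyn)))) {
    return("Indeterminant")
  }
  if (up(ct_syn) || up(ct_nonsyn)) return("Possible GoF")
  if (down(ct_syn) || down(ct_nonsyn)) return("Possible LoF")
  "no change"
}

#' Classify one variant profile against its wild-type reference
#'
#' End-to-end classification: computes the display-convention folds, the
#' per-assay graded votes, both charge-transfer composites, and the final
#' call.
#'
#' @param variant,wt One-row data frames with the columns of
#'   [synaptic_charge_transfer()] plus optional significance flags
#'   `glu_sig`, `gly_sig`, `mg_sig`, `po_sig`, `tau_sig`, `surf_sig`
#'   and a `tau_status` column.
#' @param config A [profile_config()].
#' @return A one-row tibble with `construct_id`, the six folds, the vote
#'   counts per direction and confidence, `ct_syn`, `ct_nonsyn`, `call`;
#'   the full vote table is in the `votes` list-column.
#' @export
classify_profile <- function(variant, wt, config = profile_config()) {
  variant <- as.list(variant)
  wt <- as.list(wt)
  folds <- assay_display_folds(variant, wt, config)
  sig_cols <- c(glu_potency = "glu_sig", gly_potency = "gly_sig",
                mg_ic50 = "mg_sig", po = "po_sig", tau_w = "tau_sig",
                surface = "surf_sig")
  votes <- purrr::imap_dfr(folds, function(fold, assay) {
    sig <- variant[[sig_cols[[assay]]]] %||% !is.na(fold)
    grade_assay_change(fold, assay, isTRUE(sig), config)
  })
  tau_status <- variant$tau_status %||% "measured"
  if (is.na(folds[["tau_w"]]) && identical(tau_status, "measured")) {
    tau_status <- "too_small_to_measure"
  }
  ct_syn <- synaptic_charge_transfer(variant, wt, config)
  ct_nonsyn <- nonsynaptic_charge_transfer(variant, wt, config)
  others_done <- !any(is.na(folds[setdiff(names(folds), "tau_w")]))
  call <- classify_call(votes, as.numeric(ct_syn), as.numeric(ct_nonsyn),
                        tau_status = tau_status,
                        all_other_assays_done = others_done,
                        config = config)
  n_dir <- function(d, conf) sum(votes$direction == d & votes$confidence == conf)
  tibble(
    construct_id = variant$construct_id %||% NA_character_,
    fold_glu_potency = folds[["glu_potency"]],
    fold_gly_potency = folds[["gly_potency"]],
    fold_mg_ic50 = folds[["mg_ic50"]],
    fold_po = folds[["po"]],
    fold_tau_w = folds[["tau_w"]],
    fold_surface = folds[["surface"]],
    n_gof_high = n_dir("GoF", "H"), n_gof_moderate = n_dir("GoF", "M"),
    n_lof_high = n_dir("LoF", "H"), n_lof_moderate = n_dir("LoF", "M"),
    ct_syn = as.numeric(ct_syn), ct_nonsyn = as.numeric(ct_nonsyn),
    tau_status = tau_status,
    call = call,
    votes = list(votes)
  )
}

#' Count charge-transfer folds above a threshold
#'
#' @param ct Numeric vector of charge-transfer folds (NAs are not
#'   counted).
#' @param threshold Suprathreshold bound (default 2.5).
#' @return Integer count.
#' @export
count_suprathreshold <- function(ct, threshold = 2.5) {
  sum(ct > threshold, na.rm = TRUE)
}

#' Regression of deactivation fold on glutamate-potency fold
#'
#' Ordinary least squares of `log10(tau_w fold)` on `log10(glutamate
#' EC50 fold)` across variants, restricted to variants whose EC50
#' exceeds `min_ec50` (potencies below ~30 nM can be contaminated by
#' ambient agonist).
#'
#' @param data A tibble with columns `tau_w`, `wt_tau_w`, `glu_ec50`,
#'   `wt_glu_ec50` (per-variant values and matched wild-type references).
#' @param min_ec50 Inclusion threshold on the variant EC50, uM.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_tau_vs_ec50 <- function(data, min_ec50 = 0.03) {
  assert_columns(data, c("tau_w", "wt_tau_w", "glu_ec50", "wt_glu_ec50"))
  d <- data |>
    filter(!is.na(.data$tau_w), !is.na(.data$glu_ec50),
           .data$glu_ec50 > min_ec50) |>
    mutate(x = log10(.data$glu_ec50 / .data$wt_glu_ec50),
           y = log10(.data$tau_w / .data$wt_tau_w))
  fold_regression(d)
}

#' Regression between glycine- and glutamate-potency folds
#'
#' Ordinary least squares on the log10 fold changes of the two agonist
#' potencies.  Both orientations are available because the printed
#' slope/axes pairing of such plots is ambiguous: `"gly_on_glu"`
#' regresses the glycine fold on the glutamate fold, `"glu_on_gly"` the
#' reverse.  The default filter keeps variants whose EC50 for both
#' agonists exceeds `min_ec50`.
#'
#' @param data A tibble with `gly_ec50`, `wt_gly_ec50`, `glu_ec50`,
#'   `wt_glu_ec50`.
#' @param orientation Which variable is the response.
#' @param min_ec50 Inclusion threshold, uM.
#' @param filter_on Apply the threshold to `"both"` agonists or to
#'   `"glutamate"` only.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_gly_vs_glu <- function(data,
                               orientation = c("gly_on_glu", "glu_on_gly"),
                               min_ec50 = 0.03,
                               filter_on = c("both", "glutamate")) {
  orientation <- match.arg(orientation)
  filter_on <- match.arg(filter_on)
  assert_columns(data, c("gly_ec50", "wt_gly_ec50", "glu_ec50",
                         "wt_glu_ec50"))
  d <- data |>
    filter(!is.na(.data$glu_ec50), !is.na(.data$gly_ec50),
           .data$glu_ec50 > min_ec50)
  if (filter_on == "both") d <- filter(d, .data$gly_ec50 > min_ec50)
  d <- mutate(d,
              fold_glu = log10(.data$glu_ec50 / .data$wt_glu_ec50),
              fold_gly = log10(.data$gly_ec50 / .data$wt_gly_ec50))
  if (orientation == "gly_on_glu") {
    d <- mutate(d, x = .data$fold_glu, y = .data$fold_gly)
  } else {
    d <- mutate(d, x = .data$fold_gly, y = .data$fold_glu)
  }
  fold_regression(d)
}

fold_regression <- function(d) {
  if (nrow(d) < 3) abort("Need at least 3 variants for the regression.")
  if (sd(d$x) == 0) abort("Degenerate regressor: no variance in the fold changes.")
  f <- lm(y ~ x, data = d)
  tibble(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
         r_squared = summary(f)$r.squared, n = nrow(d))
}

#' Predicted EC50 under a two-state gating model
#'
#' A simple occupancy argument for receptors in which binding and gating
#' are sequential: stronger gating (larger normalized open probability
#' `po = E / (1 + E)` for gating equilibrium `E`) pulls the apparent
#' EC50 below the intrinsic binding affinity, `EC50 = Kd * (1 - po)`.
#' This is a generic stand-in relation for exploring the potency/open-
#' probability trend, not a mechanistic receptor model.
#'
#' @param po Normalized gating open probability, in \[0, 1).
#' @param kd Intrinsic agonist dissociation constant, uM.
#' @return Predicted EC50, uM.
#' @export
#' @examples
#' ec50_po_relation(0.5, 10)  # Kd/2
ec50_po_relation <- function(po, kd) {
  if (any(po >= 1) || any(po < 0)) abort("`po` must be in [0, 1).")
  if (any(kd <= 0)) abort("`kd` must be strictly positive.")
  kd * (1 - po)
}

#' Ledger-style plot of per-variant classification calls
#'
#' @param classification A tibble from [classify_profile()] rows.
#' @return A ggplot tile ledger of display folds coloured by direction.
#' @export
plot_classification_ledger <- function(classification) {
  assert_columns(classification, c("construct_id", "call"))
  long <- classification |>
    select("construct_id", dplyr::starts_with("fold_")) |>
    tidyr::pivot_longer(dplyr::starts_with("fold_"),
                        names_to = "assay", values_to = "fold",
                        names_prefix = "fold_")
  ggplot2::ggplot(long, ggplot2::aes(.data$assay, .data$construct_id,
                                     fill = log10(.data$fold))) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$fold, 2)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0,
                                  na.value = "grey85",
                                  name = "log10 fold") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
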