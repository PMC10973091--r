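#' Run the full profiling pipeline on an assay panel
#'
#' Executes every analysis stage in dependency order on a panel of raw
#' per-cell assay data (as produced by [sim_variant_panel()] or read
#' from equivalent CSVs): Hill fits of the glutamate, glycine and Mg2+
#' concentration-response series; biexponential deactivation fits and
#' weighted-tau summaries; open-probability and surface-expression
#' summaries; the reversal-potential permeability screen; and finally
#' the per-variant charge-transfer composites and classification calls
#' against the designated wild-type reference construct.
#'
#' Significance flags feeding the classifier are 95% confidence-interval
#' non-overlap for the fitted potencies, Welch t-tests (p < 0.05) on the
#' per-cell open-probability and weighted-tau values, and a 1.5-fold
#' deviation rule for the surface-expression ratio.
#'
#' The pipeline itself is deterministic: re-running it on identical
#' inputs reproduces identical outputs (and identical CSV bytes when
#' `out_dir` is set).
#'
#' @param panel A named list with tibbles `cr_series`, `traces`,
#'   `mtsea`, `iv`, `expression` (see [sim_variant_panel()] for the
#'   schemas) and optionally `t_app` (ms, end of the agonist
#'   application window for the traces).
#' @param wt_construct `construct_id` of the same-day wild-type
#'   reference present in the panel.
#' @param config A [profile_config()].
#' @param out_dir Optional directory; when given, every stage table is
#'   written as CSV (`fits.csv`, `kinetics.csv`, `props.csv`,
#'   `permeability.csv`, `classification.csv`) together with a
#'   plain-text ledger embedding the configuration.
#' @return A named list of tibbles: `fits`, `kinetics`, `props`,
#'   `permeability`, `profiles`, `classification`.
#' @export
run_profile_pipeline <- function(panel, wt_construct,
                                 config = profile_config(),
                                 out_dir = NULL) {
  required <- c("cr_series", "traces", "mtsea", "expression")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(sprintf("Panel is missing input table(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  constructs <- unique(panel$cr_series$construct_id)
  if (!wt_construct %in% constructs) {
    abort(sprintf("Wild-type construct '%s' not found in the panel.",
                  wt_construct))
  }
  t_app <- panel$t_app %||% attr(panel$traces, "application_window")[2] %||% 10
  app_win <- c(0, t_app)

  ## stage 1: concentration-response fits -------------------------------
  fits <- panel$cr_series |>
    group_by(.data$construct_id, .data$ligand) |>
    dplyr::group_map(function(d, key) {
      mode <- if (key$ligand == "Mg") "inhibitor" else "agonist"
      f <- fit_hill(d, mode = mode)
      mutate(glance(f), construct_id = key$construct_id,
             ligand = key$ligand, mode = mode, .before = 1)
    }) |>
    bind_rows()

  ## stage 2: deactivation kinetics --------------------------------------
  kin <- purrr::map(setNames(constructs, constructs), function(cc) {
    tr <- filter(panel$traces, .data$construct_id == cc)
    if (nrow(tr) == 0) return(NULL)
    summarise_deactivation(tr, application_window = app_win)
  })
  kinetics <- purrr::imap_dfr(kin, function(x, cc) {
    if (is.null(x)) return(NULL)
    mutate(x$summary, construct_id = cc, .before = 1)
  })

  ## stage 3: channel properties -----------------------------------------
  po_cells <- panel$mtsea |>
    group_by(.data$construct_id) |>
    dplyr::group_modify(function(d, key) {
      open_probability(d$i_control_nA, d$i_mtsea_nA, config$gamma_ratio)
    }) |>
    ungroup()
  props <- panel$mtsea |>
    group_by(.data$construct_id) |>
    dplyr::group_modify(function(d, key) summarise_open_probability(d, config$gamma_ratio)) |>
    ungroup()
  wt_plate <- filter(panel$expression, .data$construct_id == wt_construct)
  surf <- purrr::map_dfr(setNames(constructs, constructs), function(cc) {
    plate <- filter(panel$expression, .data$construct_id == cc)
    if (nrow(plate) == 0) return(tibble(construct_id = cc, surface_ratio = NA_real_))
    tibble(construct_id = cc,
           surface_ratio = expression_ratio_from_plates(plate, wt_plate))
  })
  props <- left_join(props, surf, by = "construct_id")

  ## stage 4: permeability screen ----------------------------------------
  permeability <- NULL
  if (!is.null(panel$iv) && nrow(panel$iv) > 0) {
    dv <- panel$iv |>
      group_by(.data$construct_id) |>
      dplyr::group_modify(function(d, key) summarise_dv_rev(d)) |>
      ungroup()
    wt_dv <- dv$dv_rev_mean[dv$construct_id == wt_construct]
    permeability <- dv |>
      dplyr::rowwise() |>
      dplyr::group_map(function(d, ...) {
        mutate(ddv_rev_screen(d$dv_rev_mean, wt_dv, config$ddv_threshold_mV),
               construct_id = d$construct_id,
               dv_rev_sem = d$dv_rev_sem, n = d$n, .before = 1)
      }) |>
      bind_rows()
  }

  ## stage 5: assemble profiles and classify -----------------------------
  get_fit <- function(cc, lig, what) {
    row <- fits[fits$construct_id == cc & fits$ligand == lig, ]
    if (nrow(row) == 0) return(NA_real_)
    row[[what]][1]
  }
  profiles <- purrr::map_dfr(setNames(constructs, constructs), function(cc) {
    k <- kinetics[kinetics$construct_id == cc, ]
    p <- props[props$construct_id == cc, ]
    tau_status <- if (nrow(k) == 0) "not_available"
      else if (k$n == 0 || k$n_too_small > k$n) "too_small_to_measure"
      else "measured"
    tibble(
      construct_id = cc,
      ec50_glu = get_fit(cc, "glutamate", "potency_uM"),
      hill_glu = get_fit(cc, "glutamate", "hill_n"),
      glu_ci_low = get_fit(cc, "glutamate", "ci_low"),
      glu_ci_high = get_fit(cc, "glutamate", "ci_high"),
      ec50_gly = get_fit(cc, "glycine", "potency_uM"),
      hill_gly = get_fit(cc, "glycine", "hill_n"),
      gly_ci_low = get_fit(cc, "glycine", "ci_low"),
      gly_ci_high = get_fit(cc, "glycine", "ci_high"),
      ic50_mg = get_fit(cc, "Mg", "potency_uM"),
      hill_mg = get_fit(cc, "Mg", "hill_n"),
      mg_ci_low = get_fit(cc, "Mg", "ci_low"),
      mg_ci_high = get_fit(cc, "Mg", "ci_high"),
      po = if (nrow(p)) p$po_mean else NA_real_,
      tau_w = if (nrow(k) && tau_status == "measured") k$tau_weighted_mean else NA_real_,
      peak = if (nrow(k) && tau_status == "measured") k$peak_mean else NA_real_,
      surface_ratio = if (nrow(p)) p$surface_ratio else NA_real_,
      tau_status = tau_status
    )
  })

  wt_profile <- profiles[profiles$construct_id == wt_construct, ]
  welch_sig <- function(x, y) {
    if (length(x) < 3 || length(y) < 3 || (sd(x) == 0 && sd(y) == 0)) {
      return(FALSE)
    }
    isTRUE(tryCatch(t.test(x, y)$p.value < 0.05, error = function(e) FALSE))
  }
  cells_of <- function(tbl, cc, col) tbl[[col]][tbl$construct_id == cc]

  classification <- purrr::map_dfr(constructs, function(cc) {
    v <- profiles[profiles$construct_id == cc, ]
    is_wt <- cc == wt_construct
    v$glu_sig <- !is_wt && isTRUE(ci_nonoverlap_significant(
      c(v$glu_ci_low, v$glu_ci_high),
      c(wt_profile$glu_ci_low, wt_profile$glu_ci_high))$significant)
    v$gly_sig <- !is_wt && isTRUE(ci_nonoverlap_significant(
      c(v$gly_ci_low, v$gly_ci_high),
      c(wt_profile$gly_ci_low, wt_profile$gly_ci_high))$significant)
    v$mg_sig <- !is_wt && isTRUE(ci_nonoverlap_significant(
      c(v$mg_ci_low, v$mg_ci_high),
      c(wt_profile$mg_ci_low, wt_profile$mg_ci_high))$significant)
    v$po_sig <- !is_wt && welch_sig(cells_of(po_cells, cc, "po"),
                                    cells_of(po_cells, wt_construct, "po"))
    tau_cells <- purrr::map(kin[c(cc, wt_construct)], function(x) {
      if (is.null(x)) numeric(0)
      else x$per_cell$tau_weighted[x$per_cell$status %in% c("ok", "single_exponential")]
    })
    v$tau_sig <- !is_wt && welch_sig(tau_cells[[1]], tau_cells[[2]])
    v$surf_sig <- !is_wt && !is.na(v$surface_ratio) &&
      abs(log(v$surface_ratio)) > log(1.5)
    classify_profile(v, wt_profile, config)
  })

  result <- list(fits = fits, kinetics = kinetics, props = props,
                 permeability = permeability, profiles = profiles,
                 classification = classification)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage_write <- function(tbl, file) {
      if (!is.null(tbl)) {
        readr::write_csv(dplyr::select(tbl, -dplyr::any_of("votes")),
                         file.path(out_dir, file))
      }
    }
    stage_write(fits, "fits.csv")
    stage_write(kinetics, "kinetics.csv")
    stage_write(props, "props.csv")
    stage_write(permeability, "permeability.csv")
    stage_write(classification, "classification.csv")
    ledger <- c(
      "grinfun classification ledger",
      sprintf("wild-type reference: %s", wt_construct),
      "configuration:",
      sprintf("  %s = %s", names(config),
              purrr::map_chr(config, ~ format(.x, digits = 6))),
      "",
      sprintf("%-28s ct_syn %10s  ct_nonsyn %10s  call %s",
              "construct", "", "", ""),
      purrr::pmap_chr(classification[c("construct_id", "ct_syn",
                                       "ct_nonsyn", "call")],
                      function(construct_id, ct_syn, ct_nonsyn, call) {
                        sprintf("%-28s %10s  %10s  %s", construct_id,
                                format(signif(ct_syn, 3)),
                                format(signif(ct_nonsyn, 3)), call)
                      }))
    writeLines(ledger, file.path(out_dir, "ledger.txt"))
  }
  result
}
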