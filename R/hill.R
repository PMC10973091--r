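#' Fit a Hill concentration-response curve
#'
#' Least-squares fit of the Hill model to pooled concentration-response
#' points.  Agonist mode fits `100 / (1 + (EC50/c)^N)`; inhibitor mode
#' fits `(100 - minimum) / (1 + (c/IC50)^N) + minimum` with the residual
#' `minimum` constrained to be non-negative by default.  The potency is
#' parameterized as `log10(EC50)` (or `log10(IC50)`), and the 95%
#' confidence interval is a normal (z-based) interval on that log
#' parameter, back-transformed to concentration - the convention used for
#' composite oocyte concentration-response curves.
#'
#' With `normalize = "fitted_max"` (agonist mode) each cell is first fit
#' with a free maximum and its responses rescaled to percent of that
#' fitted maximum before pooling; cells with fewer than 4 points, or
#' failed per-cell fits, are pooled unscaled.
#'
#' @param data A data frame with columns `concentration_uM`,
#'   `response_pct` and optionally `cell_id` (needed for per-cell
#'   normalization).
#' @param mode `"agonist"` or `"inhibitor"`.
#' @param constrain_minimum Keep the inhibitor-mode residual response
#'   `minimum >= 0` (default, matching the fitting convention for
#'   channel blockers).
#' @param normalize `"fitted_max"` or `"none"`.
#' @param conf_level Confidence level for the potency interval.
#' @return An object of class `hill_fit` with elements `mode`,
#'   `potency_uM`, `log10_potency`, `se_log10`, `hill_n`, `minimum_pct`,
#'   `ci_low`, `ci_high`, `n_cells`, `n_points`, `converged`, `flags`.
#' @export
#' @examples
#' d <- tibble::tibble(concentration_uM = 10^seq(-2, 2, 0.5) * 3.5)
#' d$response_pct <- hill_response(d$concentration_uM, 3.5, 1.2)
#' fit_hill(d)$potency_uM
fit_hill <- function(data,
                     mode = c("agonist", "inhibitor"),
                     constrain_minimum = TRUE,
                     normalize = c("fitted_max", "none"),
                     conf_level = 0.95) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  assert_columns(data, c("concentration_uM", "response_pct"))
  data <- as_tibble(data)
  if (any(data$concentration_uM <= 0)) {
    abort("Concentrations must be strictly positive.")
  }
  if (length(unique(data$concentration_uM)) < 4) {
    abort("At least 4 distinct concentrations are required for a Hill fit.")
  }
  flags <- character(0)

  if (mode == "agonist" && normalize == "fitted_max" && "cell_id" %in% names(data)) {
    data <- normalize_cells_to_fitted_max(data)
  }

  conc <- data$concentration_uM
  resp <- data$response_pct
  lc <- log10(conc)

  # crude start: concentration nearest half-max on the clean profile
  start_lp <- start_log10_potency(conc, resp, mode)
  fit <- NULL
  converged <- TRUE
  if (mode == "agonist") {
    # The composite curve is fit with a free shared maximum and the
    # responses expressed as percent of that fitted maximum; fixing the
    # maximum at the nominal 100 would transfer scale noise into the
    # potency estimate.
    fit <- try(minpack.lm::nlsLM(
      resp ~ top / (1 + 10^(n * (lp - lc))),
      start = list(top = max(100, max(resp)), lp = start_lp, n = 1),
      lower = c(top = 1e-6, lp = min(lc) - 3, n = 0.05),
      upper = c(top = Inf, lp = max(lc) + 3, n = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    min_pct <- 0
  } else {
    lower_min <- if (constrain_minimum) 0 else -100
    fit <- try(minpack.lm::nlsLM(
      resp ~ minimum + (100 - minimum) / (1 + 10^(n * (lc - lp))),
      start = list(lp = start_lp, n = 1, minimum = 0.5),
      lower = c(lp = min(lc) - 3, n = 0.05, minimum = lower_min),
      upper = c(lp = max(lc) + 3, n = 10, minimum = 99),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }

  if (inherits(fit, "try-error")) {
    converged <- FALSE
    flags <- c(flags, "non_convergence")
    est <- c(lp = NA_real_, n = NA_real_)
    se_lp <- NA_real_
    min_pct <- NA_real_
  } else {
    est <- coef(fit)
    se_lp <- tryCatch(summary(fit)$coefficients["lp", "Std. Error"],
                      error = function(e) NA_real_)
    min_pct <- if (mode == "inhibitor") unname(est["minimum"]) else 0
    if (est["lp"] > max(lc) + 1 || est["lp"] < min(lc) - 1) {
      flags <- c(flags, "potency_outside_range")
    }
    if (mode == "inhibitor") {
      # monotonicity check: pooled responses should not rise with dose
      med <- tapply(resp, conc, median)
      if (any(diff(med) > 15)) flags <- c(flags, "non_monotonic")
    }
  }

  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(mode = mode,
         potency_uM = unname(10^est["lp"]),
         log10_potency = unname(est["lp"]),
         se_log10 = unname(se_lp),
         hill_n = unname(est["n"]),
         fitted_max = if (mode == "agonist") unname(est["top"]) else 100,
         minimum_pct = min_pct,
         ci_low = unname(10^(est["lp"] - z * se_lp)),
         ci_high = unname(10^(est["lp"] + z * se_lp)),
         conf_level = conf_level,
         n_cells = if ("cell_id" %in% names(data)) length(unique(data$cell_id)) else 1L,
         n_points = length(resp),
         converged = converged,
         flags = flags,
         data = data,
         model = if (inherits(fit, "try-error")) NULL else fit),
    class = "hill_fit")
}

# Per-cell normalization to the fitted maximum, done in two passes so
# the potency estimate stays unbiased: a preliminary pooled free-maximum
# fit supplies the curve shape; each cell's maximum is then the linear
# projection of its responses onto that shape (an unbiased scale
# estimate using every concentration), and cells are rescaled to the
# geometric mean of the per-cell maxima before the final pooled fit.
# Rescaling each cell to its own noisy 3-parameter maximum instead
# would push the pooled potency estimate systematically off.
normalize_cells_to_fitted_max <- function(data) {
  lc <- log10(data$concentration_uM)
  resp <- data$response_pct
  prelim <- try(minpack.lm::nlsLM(
    resp ~ top / (1 + 10^(n * (lp - lc))),
    start = list(top = max(resp), lp = stats::median(lc), n = 1),
    lower = c(top = 1e-6, lp = min(lc) - 3, n = 0.05),
    upper = c(top = Inf, lp = max(lc) + 3, n = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(prelim, "try-error")) return(data)
  cf <- coef(prelim)
  shape <- 1 / (1 + 10^(cf[["n"]] * (cf[["lp"]] - lc)))
  tops <- data |>
    mutate(.shape = shape) |>
    group_by(.data$cell_id) |>
    summarise(top = sum(.data$.shape * .data$response_pct) /
                sum(.data$.shape^2), .groups = "drop")
  tops <- filter(tops, is.finite(.data$top), .data$top > 0)
  if (nrow(tops) == 0) return(data)
  ref <- exp(mean(log(tops$top)))
  data |>
    left_join(tops, by = "cell_id") |>
    mutate(response_pct = if_else(is.na(.data$top), .data$response_pct,
                                  .data$response_pct * ref / .data$top)) |>
    select(-"top")
}

start_log10_potency <- function(conc, resp, mode) {
  med <- tapply(resp, conc, mean)
  target <- if (mode == "agonist") max(med) / 2 else (max(med) + min(med)) / 2
  log10(as.numeric(names(med))[which.min(abs(med - target))])
}

#' Fit the agonist Hill equation to a set of concentration-response series
#'
#' Thin wrappers around [fit_hill()] with the mode fixed; provided so that
#' pipelines read naturally.
#'
#' @inheritParams fit_hill
#' @return A `hill_fit`.
#' @export
fit_agonist <- function(data, normalize = "fitted_max", conf_level = 0.95) {
  fit_hill(data, mode = "agonist", normalize = normalize,
           conf_level = conf_level)
}

#' @rdname fit_agonist
#' @export
fit_inhibitor <- function(data, constrain_minimum = TRUE, conf_level = 0.95) {
  fit_hill(data, mode = "inhibitor", constrain_minimum = constrain_minimum,
           normalize = "none", conf_level = conf_level)
}

#' @export
print.hill_fit <- function(x, ...) {
  lab <- if (x$mode == "agonist") "EC50" else "IC50"
  cat(sprintf("<hill_fit> %s %.4g uM [%.4g, %.4g], N = %.3g", lab,
              x$potency_uM, x$ci_low, x$ci_high, x$hill_n))
  if (x$mode == "inhibitor") cat(sprintf(", minimum = %.3g%%", x$minimum_pct))
  cat(sprintf("  (%d cells, %d points)\n", x$n_cells, x$n_points))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a Hill fit into a one-row-per-term tibble
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(
    term = c(if (x$mode == "agonist") "ec50_uM" else "ic50_uM",
             "hill_n", "minimum_pct"),
    estimate = c(x$potency_uM, x$hill_n, x$minimum_pct),
    conf.low = c(x$ci_low, NA, NA),
    conf.high = c(x$ci_high, NA, NA)
  )
}

#' One-row model summary of a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(potency_uM = x$potency_uM, ci_low = x$ci_low, ci_high = x$ci_high,
         hill_n = x$hill_n, minimum_pct = x$minimum_pct,
         n_cells = x$n_cells, n_points = x$n_points,
         converged = x$converged,
         flags = paste(x$flags, collapse = ";"))
}

#' Plot a Hill fit with its pooled data
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, ...) {
  rng <- range(object$data$concentration_uM)
  grid <- tibble(concentration_uM = 10^seq(log10(rng[1]), log10(rng[2]),
                                           length.out = 200))
  grid$response_pct <- hill_response(grid$concentration_uM,
                                     object$potency_uM, object$hill_n,
                                     object$mode, object$minimum_pct %||% 0)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$concentration_uM, .data$response_pct)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (uM)", y = "Response (% max)") +
    ggplot2::theme_classic()
}

#' Relative response ratio between two agonist fits at a concentration
#'
#' Evaluates the fitted agonist Hill curve of a variant and of the
#' wild-type reference at one physiological concentration and returns the
#' ratio variant/wild-type.  These ratios are the R_GLY and R_GLU terms
#' of the charge-transfer composites: glycine at 3 uM, glutamate at
#' 1000 uM (synaptic) or 0.1 uM (non-synaptic ambient).
#'
#' @param fit_variant,fit_wt Agonist-mode `hill_fit` objects for the same
#'   ligand.
#' @param concentration Evaluation concentration, uM.
#' @return Dimensionless ratio.
#' @export
relative_response_ratio <- function(fit_variant, fit_wt, concentration) {
  stopifnot(inherits(fit_variant, "hill_fit"), inherits(fit_wt, "hill_fit"))
  if (fit_variant$mode != "agonist" || fit_wt$mode != "agonist") {
    abort("Both fits must be agonist-mode.")
  }
  response_ratio_at(fit_variant$potency_uM, fit_variant$hill_n,
                    fit_wt$potency_uM, fit_wt$hill_n, concentration)
}

# parameter-level version used by the classification stage
response_ratio_at <- function(ec50_v, hill_v, ec50_wt, hill_wt,
                              concentration) {
  if (is.na(hill_v)) {
    warn("Missing variant Hill slope; falling back to N = 1.")
    hill_v <- 1
  }
  if (is.na(hill_wt)) {
    warn("Missing wild-type Hill slope; falling back to N = 1.")
    hill_wt <- 1
  }
  hill_response(concentration, ec50_v, hill_v) /
    hill_response(concentration, ec50_wt, hill_wt)
}

#' Percent inhibition predicted by an inhibitor fit at a concentration
#'
#' `100 - response(concentration)` under the fitted inhibition curve;
#' the default 1000 uM evaluates the physiological 1 mM Mg2+ block term.
#'
#' @param fit An inhibitor-mode `hill_fit`, or a number interpreted as an
#'   IC50 with Hill slope 1 and zero minimum.
#' @param concentration Inhibitor concentration, uM.
#' @param hill,minimum Used only when `fit` is a bare IC50.
#' @return Percent inhibition in \[0, 100\].
#' @export
#' @examples
#' percent_inhibition_at(19)          # 1 mM Mg2+ over a 19 uM IC50
percent_inhibition_at <- function(fit, concentration = 1000, hill = 1,
                                  minimum = 0) {
  if (inherits(fit, "hill_fit")) {
    if (fit$mode != "inhibitor") abort("`fit` must be an inhibitor-mode fit.")
    ic50 <- fit$potency_uM
    hill <- fit$hill_n
    minimum <- fit$minimum_pct
  } else {
    ic50 <- fit
  }
  if (concentration == 0) return(0)
  100 - hill_response(concentration, ic50, hill, "inhibitor", minimum)
}

#' Significance by 95% confidence-interval non-overlap
#'
#' Two potency estimates are called significantly different when their
#' 95% confidence intervals are disjoint; potency moves inversely to
#' EC50/IC50, so a variant interval entirely below the reference interval
#' means increased potency.
#'
#' @param fit_variant,fit_wt `hill_fit` objects, or length-2 numeric
#'   intervals `c(low, high)`.
#' @return A list with `significant` (logical) and `direction`
#'   (`"increased_potency"`, `"decreased_potency"`, or `NA`).
#' @export
#' @examples
#' ci_nonoverlap_significant(c(1.2, 1.4), c(3.4, 3.6))
ci_nonoverlap_significant <- function(fit_variant, fit_wt) {
  iv <- ci_interval(fit_variant)
  iw <- ci_interval(fit_wt)
  if (any(is.na(c(iv, iw)))) {
    return(list(significant = NA, direction = NA_character_))
  }
  if (iv[2] < iw[1]) {
    list(significant = TRUE, direction = "increased_potency")
  } else if (iv[1] > iw[2]) {
    list(significant = TRUE, direction = "decreased_potency")
  } else {
    list(significant = FALSE, direction = NA_character_)
  }
}

ci_interval <- function(x) {
  if (inherits(x, "hill_fit")) c(x$ci_low, x$ci_high)
  else if (is.numeric(x) && length(x) == 2) sort(x)
  else abort("Expected a hill_fit or a length-2 numeric interval.")
}
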