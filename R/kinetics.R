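#' Fit the biexponential deactivation time course of a current trace
#'
#' Locates the peak inside the agonist application window, estimates the
#' baseline noise from the pre-application samples, and fits the decay
#' segment (starting one sample after the application ends) with the sum
#' of two exponentials
#' `A_fast exp(-t/tau_fast) + A_slow exp(-t/tau_slow)`.
#' Components are ordered so `tau_fast <= tau_slow`.  Near-degenerate
#' fits (time constants within 5%) and fits whose slow amplitude
#' collapses are refit as a single exponential, in which case the
#' weighted tau equals the single time constant.  Peaks below
#' `snr_threshold` baseline SDs return status
#' `"too_small_to_measure"` without fitting, mirroring how low-amplitude
#' recordings are reported as not determined.
#'
#' @param trace A data frame with `time_ms` and `current_pA`; the agonist
#'   application window is taken from the `"application_window"`
#'   attribute or from `application_window`.
#' @param application_window Length-2 numeric `(start, end)` in ms.
#' @param snr_threshold Peak-to-baseline-SD ratio under which the trace
#'   is declared too small to measure.
#' @param degenerate_tol Relative tau separation under which the biexp
#'   collapses to a single exponential.
#' @return An object of class `biexp_fit` with `amp_fast`, `tau_fast`,
#'   `amp_slow`, `tau_slow`, `tau_weighted`, `peak`, `rss`, `status`
#'   (`"ok"`, `"single_exponential"`, `"too_small_to_measure"`,
#'   `"non_convergence"`).
#' @export
fit_deactivation <- function(trace, application_window = NULL,
                             snr_threshold = 3, degenerate_tol = 0.05) {
  assert_columns(trace, c("time_ms", "current_pA"))
  win <- application_window %||% attr(trace, "application_window")
  if (is.null(win) || length(win) != 2) {
    abort("Supply `application_window = c(start, end)` in ms.")
  }
  t <- trace$time_ms
  i <- trace$current_pA
  dt <- median(diff(t))

  pre <- i[t < win[1]]
  base_sd <- if (length(pre) >= 5) sd(pre) else sd(i[t > max(t) - 10 * dt])
  base_mu <- if (length(pre) >= 5) mean(pre) else 0

  in_app <- t >= win[1] & t <= win[2] + dt
  peak <- max(i[in_app] - base_mu)
  if (!is.finite(peak) || (base_sd > 0 && peak < snr_threshold * base_sd)) {
    return(new_biexp_fit(status = "too_small_to_measure", peak = peak,
                         base_sd = base_sd))
  }

  dec <- t > win[2] + dt / 2
  td <- t[dec] - (win[2] + dt)
  id <- i[dec] - base_mu
  if (length(td) < 8) abort("Decay segment too short to fit.")

  # single-exponential start from the log-linear early decay
  pos <- id > max(id) * 0.02
  tau0 <- tryCatch({
    f <- lm(log(id[pos]) ~ td[pos])
    max(-1 / coef(f)[2], dt)
  }, error = function(e) max(td) / 5)
  a0 <- max(id)

  bi <- try(minpack.lm::nlsLM(
    id ~ af * exp(-td / exp(ltf)) + as * exp(-td / exp(lts)),
    start = list(af = a0 * 0.6, ltf = log(tau0 / 2),
                 as = a0 * 0.4, lts = log(tau0 * 2)),
    lower = c(af = 0, ltf = log(dt / 10), as = 0, lts = log(dt / 10)),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)

  single <- try(minpack.lm::nlsLM(
    id ~ a * exp(-td / exp(lt)),
    start = list(a = a0, lt = log(tau0)),
    lower = c(a = 0, lt = log(dt / 10)),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)

  if (inherits(bi, "try-error") && inherits(single, "try-error")) {
    return(new_biexp_fit(status = "non_convergence", peak = peak,
                         base_sd = base_sd))
  }

  use_single <- FALSE
  if (!inherits(bi, "try-error")) {
    cf <- coef(bi)
    taus <- exp(c(cf[["ltf"]], cf[["lts"]]))
    amps <- c(cf[["af"]], cf[["as"]])
    ord <- order(taus)
    taus <- taus[ord]; amps <- amps[ord]
    rel_sep <- (taus[2] - taus[1]) / taus[2]
    amp_frac_slow <- amps[2] / sum(amps)
    if (!is.finite(rel_sep) || rel_sep < degenerate_tol ||
        sum(amps) == 0 || amp_frac_slow < 0.01 || amps[1] / sum(amps) < 0.01) {
      use_single <- TRUE
    }
  } else {
    use_single <- TRUE
  }

  if (use_single) {
    if (inherits(single, "try-error")) {
      return(new_biexp_fit(status = "non_convergence", peak = peak,
                           base_sd = base_sd))
    }
    cf <- coef(single)
    tau <- exp(cf[["lt"]])
    return(new_biexp_fit(
      amp_fast = cf[["a"]], tau_fast = tau, amp_slow = 0, tau_slow = tau,
      tau_weighted = tau, peak = peak,
      rss = sum(stats::residuals(single)^2),
      status = "single_exponential", base_sd = base_sd))
  }

  new_biexp_fit(
    amp_fast = amps[1], tau_fast = taus[1],
    amp_slow = amps[2], tau_slow = taus[2],
    tau_weighted = weighted_tau(amps[1], taus[1], amps[2], taus[2]),
    peak = peak, rss = sum(stats::residuals(bi)^2),
    status = "ok", base_sd = base_sd)
}

new_biexp_fit <- function(amp_fast = NA_real_, tau_fast = NA_real_,
                          amp_slow = NA_real_, tau_slow = NA_real_,
                          tau_weighted = NA_real_, peak = NA_real_,
                          rss = NA_real_, status = "ok",
                          base_sd = NA_real_) {
  structure(list(amp_fast = amp_fast, tau_fast = tau_fast,
                 amp_slow = amp_slow, tau_slow = tau_slow,
                 tau_weighted = tau_weighted, peak = peak, rss = rss,
                 status = status, baseline_sd = base_sd),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("<biexp_fit>", x$status, "\n")
  if (x$status %in% c("ok", "single_exponential")) {
    cat(sprintf("  tau %.3g / %.3g ms (amps %.3g / %.3g), tau_w = %.4g ms, peak %.4g\n",
                x$tau_fast, x$tau_slow, x$amp_fast, x$amp_slow,
                x$tau_weighted, x$peak))
  }
  invisible(x)
}

#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble(term = c("amp_fast", "tau_fast", "amp_slow", "tau_slow",
                  "tau_weighted", "peak"),
         estimate = c(x$amp_fast, x$tau_fast, x$amp_slow, x$tau_slow,
                      x$tau_weighted, x$peak))
}

#' @export
glance.biexp_fit <- function(x, ...) {
  tibble(tau_fast = x$tau_fast, tau_slow = x$tau_slow,
         amp_fast = x$amp_fast, amp_slow = x$amp_slow,
         tau_weighted = x$tau_weighted, peak = x$peak, rss = x$rss,
         status = x$status)
}

#' Amplitude-weighted deactivation time constant
#'
#' `(A_fast tau_fast + A_slow tau_slow) / (A_fast + A_slow)` - a convex
#' combination of the two time constants, so it always lies between them.
#'
#' @param amp_fast A `biexp_fit`, or the fast amplitude.
#' @param tau_fast,amp_slow,tau_slow Components when given numerically.
#' @return Weighted tau, ms.
#' @export
#' @examples
#' weighted_tau(0.8, 30, 0.2, 100)  # 44
weighted_tau <- function(amp_fast, tau_fast = NULL, amp_slow = NULL,
                         tau_slow = NULL) {
  if (inherits(amp_fast, "biexp_fit")) {
    f <- amp_fast
    return(weighted_tau(f$amp_fast, f$tau_fast, f$amp_slow, f$tau_slow))
  }
  total <- amp_fast + amp_slow
  if (is.na(total) || total == 0) {
    abort("Weighted tau undefined: amplitudes sum to zero.")
  }
  (amp_fast * tau_fast + amp_slow * tau_slow) / total
}

#' 10-90% rise time of a current onset
#'
#' Baseline is the mean of the pre-application samples; the rise time is
#' the difference between the linearly interpolated first crossings of
#' 10% and 90% of the peak (above baseline).
#'
#' @inheritParams fit_deactivation
#' @return Rise time in ms; traces whose onset dips non-monotonically by
#'   more than 20% of peak between the two crossings carry a
#'   `"non_monotonic_onset"` flag attribute.
#' @export
rise_time_10_90 <- function(trace, application_window = NULL) {
  assert_columns(trace, c("time_ms", "current_pA"))
  win <- application_window %||% attr(trace, "application_window")
  if (is.null(win)) abort("Supply `application_window = c(start, end)`.")
  t <- trace$time_ms
  i <- trace$current_pA
  base <- if (any(t < win[1])) mean(i[t < win[1]]) else 0
  seg <- t >= win[1]
  ts <- t[seg]
  is <- i[seg] - base
  pk_idx <- which.max(is)
  peak <- is[pk_idx]
  noise <- if (any(t < win[1])) sd(i[t < win[1]]) else 0
  if (peak <= 0 || (noise > 0 && peak < 3 * noise)) {
    abort("No identifiable peak above baseline noise.")
  }
  onset_t <- ts[seq_len(pk_idx)]
  onset_i <- is[seq_len(pk_idx)]
  t10 <- first_crossing(onset_t, onset_i, 0.1 * peak)
  t90 <- first_crossing(onset_t, onset_i, 0.9 * peak)
  if (is.na(t10) || is.na(t90)) abort("Onset does not cross 10%/90% of peak.")
  out <- t90 - t10
  between <- onset_i[onset_t > t10 & onset_t < t90]
  if (length(between) > 2 && min(diff(between)) < -0.2 * peak) {
    attr(out, "flag") <- "non_monotonic_onset"
  }
  out
}

first_crossing <- function(t, y, level) {
  above <- y >= level
  k <- which(above)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1) return(t[1])
  t[k - 1] + (level - y[k - 1]) / (y[k] - y[k - 1]) * (t[k] - t[k - 1])
}

#' Extent of desensitization during a prolonged agonist application
#'
#' `1 - I_ss / I_peak`, where the steady state is the mean current over
#' the final 10% of the application window.
#'
#' @inheritParams fit_deactivation
#' @return Fraction in \[0, 1\] (can be slightly outside under noise).
#' @export
desensitization_extent <- function(trace, application_window = NULL) {
  assert_columns(trace, c("time_ms", "current_pA"))
  win <- application_window %||% attr(trace, "application_window")
  if (is.null(win)) abort("Supply `application_window = c(start, end)`.")
  t <- trace$time_ms
  i <- trace$current_pA
  base <- if (any(t < win[1])) mean(i[t < win[1]]) else 0
  in_app <- t >= win[1] & t <= win[2]
  if (sum(in_app) < 20) abort("No steady-state segment: application too short.")
  ia <- i[in_app] - base
  peak <- max(ia)
  ss_start <- win[2] - 0.1 * (win[2] - win[1])
  ss <- mean(i[t >= ss_start & t <= win[2]] - base)
  if (peak <= 0) abort("No identifiable peak during application.")
  1 - ss / peak
}

#' Charge-transfer estimate as peak times weighted tau
#'
#' @param peak Peak current (pA or pA/pF).
#' @param tau_weighted Weighted deactivation time constant, ms.
#' @return Charge transfer in pA*ms (or pA/pF*ms).
#' @export
#' @examples
#' charge_transfer_product(100, 44)  # 4400
charge_transfer_product <- function(peak, tau_weighted) {
  if (any(peak < 0) || any(tau_weighted < 0)) {
    abort("`peak` and `tau_weighted` must be non-negative.")
  }
  peak * tau_weighted
}

#' Summarise deactivation kinetics for a panel of traces
#'
#' Fits each cell's trace with [fit_deactivation()] and aggregates the
#' per-cell weighted taus (fit-then-average).
#'
#' @param traces A tibble with `cell_id`, `time_ms`, `current_pA` (and
#'   optionally `construct_id`).
#' @param application_window Length-2 numeric, ms.
#' @return A list with `per_cell` (tibble of per-cell fits) and `summary`
#'   (one row: mean, SEM, n of tau_weighted and peak).
#' @export
summarise_deactivation <- function(traces, application_window = NULL) {
  assert_columns(traces, c("cell_id", "time_ms", "current_pA"))
  win <- application_window %||% attr(traces, "application_window")
  per_cell <- traces |>
    group_by(.data$cell_id) |>
    dplyr::group_map(function(d, key) {
      f <- fit_deactivation(d, application_window = win)
      mutate(glance(f), cell_id = key$cell_id, .before = 1)
    }) |>
    bind_rows()
  ok <- filter(per_cell, .data$status %in% c("ok", "single_exponential"))
  summary <- tibble(
    n = nrow(ok),
    tau_weighted_mean = mean(ok$tau_weighted),
    tau_weighted_sem = sd(ok$tau_weighted) / sqrt(nrow(ok)),
    peak_mean = mean(ok$peak),
    peak_sem = sd(ok$peak) / sqrt(nrow(ok)),
    n_too_small = sum(per_cell$status == "too_small_to_measure")
  )
  list(per_cell = per_cell, summary = summary)
}
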