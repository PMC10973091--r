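# Independent brute-force oracle for the agonist Hill fit: dense grid
# search over (log10 EC50, N) minimizing the residual sum of squares with
# the maximum fixed at 100.  Used only on noiseless data, where it must
# agree with the analytic least-squares fit.
grid_search_hill <- function(conc, resp,
                             lp_range = log10(range(conc)) + c(-1, 1),
                             n_range = c(0.3, 3),
                             n_grid = 121, refinements = 4) {
  best <- c(lp = NA_real_, n = NA_real_)
  for (r in seq_len(refinements)) {
    lps <- seq(lp_range[1], lp_range[2], length.out = n_grid)
    ns <- seq(n_range[1], n_range[2], length.out = n_grid)
    rss <- outer(lps, ns, Vectorize(function(lp, n) {
      pred <- 100 / (1 + 10^(n * (lp - log10(conc))))
      sum((resp - pred)^2)
    }))
    idx <- arrayInd(which.min(rss), dim(rss))
    best <- c(lp = lps[idx[1]], n = ns[idx[2]])
    dl <- diff(lp_range) / (n_grid - 1)
    dn <- diff(n_range) / (n_grid - 1)
    lp_range <- best[["lp"]] + c(-2, 2) * dl
    n_range <- pmax(best[["n"]] + c(-2, 2) * dn, 0.05)
  }
  c(ec50 = 10^best[["lp"]], n = best[["n"]])
}

# Quiet wild-type presets used across tests.
wt2a <- function() grinfun::preset_profile("wt_glun1_2a")
wt2b <- function() grinfun::preset_profile("wt_glun1_2b")

# one-row assay profile used by the classification tests
make_profile <- function(construct_id = "X", ec50_glu = 3.5, hill_glu = 1,
                         ec50_gly = 1.2, hill_gly = 1, ic50_mg = 19,
                         hill_mg = 1, po = 0.24, tau_w = 44,
                         surface_ratio = 1, ...) {
  tibble::tibble(construct_id = construct_id, ec50_glu = ec50_glu,
                 hill_glu = hill_glu, ec50_gly = ec50_gly,
                 hill_gly = hill_gly, ic50_mg = ic50_mg, hill_mg = hill_mg,
                 po = po, tau_w = tau_w, surface_ratio = surface_ratio, ...)
}
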