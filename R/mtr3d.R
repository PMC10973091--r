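#' Residue coordinates from a structure file
#'
#' Reads a PDB file and returns one representative point per resolved
#' residue (the alpha-carbon).
#'
#' @param path Path to a PDB file.
#' @param chains Optional character vector of chain identifiers to keep.
#' @return A tibble with `chain`, `resno`, `x`, `y`, `z`.
#' @export
read_structure_residues <- function(path, chains = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Reading PDB files requires the 'bio3d' package.")
  }
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  out <- tibble(chain = ca$chain, resno = ca$resno,
                x = ca$x, y = ca$y, z = ca$z) |>
    dplyr::distinct(.data$chain, .data$resno, .keep_all = TRUE)
  if (!is.null(chains)) out <- filter(out, .data$chain %in% chains)
  out
}

#' Spatial residue neighborhoods
#'
#' For every resolved residue, the `k` nearest resolved residues by
#' Euclidean distance between representative points, plus the residue
#' itself - a 31-residue window at the default `k = 30`.  Ties are broken
#' by (distance, chain, residue index) lexicographic order so the
#' neighborhoods are deterministic.
#'
#' @param coords A tibble with `chain`, `resno`, `x`, `y`, `z` (one row
#'   per resolved residue).  Rows with missing coordinates are excluded
#'   with a warning.
#' @param k Number of neighbors (excluding the central residue).
#' @return A tibble with `chain`, `resno`, `n_window`, and a `neighbors`
#'   list-column of `chain:resno` keys (central residue included).
#' @export
residue_neighborhoods <- function(coords, k = 30) {
  assert_columns(coords, c("chain", "resno", "x", "y", "z"))
  assert_number(k, "k", lower = 0)
  unresolved <- !complete.cases(coords[, c("x", "y", "z")])
  if (any(unresolved)) {
    warn(sprintf("%d unresolved residue(s) excluded from the neighborhood graph.",
                 sum(unresolved)))
    coords <- coords[!unresolved, , drop = FALSE]
  }
  coords <- arrange(as_tibble(coords), .data$chain, .data$resno)
  n <- nrow(coords)
  keys <- paste(coords$chain, coords$resno, sep = ":")
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  k_eff <- min(k, n - 1)
  neighbors <- purrr::map(seq_len(n), function(i) {
    ord <- order(d[i, ], coords$chain, coords$resno)
    keys[ord[seq_len(k_eff + 1)]]  # self has distance 0, always first
  })
  tibble(chain = coords$chain, resno = coords$resno,
         n_window = k_eff + 1L, neighbors = neighbors)
}

#' Missense tolerance ratio of a pooled count window
#'
#' The ratio of the observed missense fraction to the expected missense
#' fraction, `[obs_mis/(obs_mis+obs_syn)] / [exp_mis/(exp_mis+exp_syn)]`,
#' over counts pooled across a window; 1 means variation as tolerated as
#' the null mutational model expects, values toward 0 mean missense
#' depletion (intolerance).  Invariant to scaling all expected counts by
#' a constant.
#'
#' @param obs_mis,obs_syn Observed missense and synonymous counts.
#' @param exp_mis,exp_syn Expected counts under the null model; the
#'   expected missense fraction must be positive.
#' @return The tolerance score (>= 0), or `NA` with a warning for an
#'   empty window.
#' @export
#' @examples
#' mtr_score(10, 30, 30, 30)  # 0.5
mtr_score <- function(obs_mis, obs_syn, exp_mis, exp_syn) {
  om <- sum(obs_mis); os <- sum(obs_syn)
  em <- sum(exp_mis); es <- sum(exp_syn)
  if (em + es <= 0 || em <= 0) {
    warn("Empty or degenerate window: expected counts are zero.")
    return(NA_real_)
  }
  if (om + os == 0) {
    warn("Empty window: no observed variants.")
    return(NA_real_)
  }
  (om / (om + os)) / (em / (em + es))
}

#' 3D-windowed missense tolerance map over a structure
#'
#' Scores each residue by the tolerance ratio of its spatial window (the
#' residue plus its `k` nearest neighbors in 3D).  Counts are pooled
#' across the window before ratioing by default; `aggregate =
#' "mean_ratio"` instead averages the per-residue ratios across the
#' window.
#'
#' @param coords Residue coordinates (`chain`, `resno`, `x`, `y`, `z`).
#' @param counts Per-residue variant counts: `chain`, `resno`,
#'   `obs_mis`, `obs_syn`, `exp_mis`, `exp_syn`.
#' @param k Neighbors per window (default 30, a 31-residue window).
#' @param aggregate `"pooled"` or `"mean_ratio"`.
#' @return A tibble with `chain`, `resno`, `n_window`, `mtr`.
#' @export
mtr3d_map <- function(coords, counts, k = 30,
                      aggregate = c("pooled", "mean_ratio")) {
  aggregate <- match.arg(aggregate)
  assert_columns(counts, c("chain", "resno", "obs_mis", "obs_syn",
                           "exp_mis", "exp_syn"))
  nb <- residue_neighborhoods(coords, k)
  keys <- paste(nb$chain, nb$resno, sep = ":")
  count_keys <- paste(counts$chain, counts$resno, sep = ":")
  missing <- setdiff(keys, count_keys)
  if (length(missing) > 0) {
    abort(sprintf(
      "Structure and counts are not reconciled; %d residue(s) lack counts: %s%s",
      length(missing), paste(head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..." else ""))
  }
  idx <- match(keys, count_keys)
  cnt <- counts[idx, c("obs_mis", "obs_syn", "exp_mis", "exp_syn")]
  scores <- purrr::map_dbl(nb$neighbors, function(nbr) {
    rows <- match(nbr, keys)
    if (aggregate == "pooled") {
      mtr_score(cnt$obs_mis[rows], cnt$obs_syn[rows],
                cnt$exp_mis[rows], cnt$exp_syn[rows])
    } else {
      mean(purrr::map_dbl(rows, function(r) {
        mtr_score(cnt$obs_mis[r], cnt$obs_syn[r],
                  cnt$exp_mis[r], cnt$exp_syn[r])
      }), na.rm = TRUE)
    }
  })
  tibble(chain = nb$chain, resno = nb$resno, n_window = nb$n_window,
         mtr = scores)
}

#' Synthetic ideal-helix residue coordinates
#'
#' Alpha-carbon positions of an ideal alpha helix (100 degrees of twist
#' and 1.5 angstrom of rise per residue on a 2.3 angstrom radius) - a
#' geometry fixture for neighborhood and tolerance-map tests.
#'
#' @param n_res Number of residues.
#' @param chain Chain identifier.
#' @param rise,twist_deg,radius Helix geometry parameters.
#' @return A tibble with `chain`, `resno`, `x`, `y`, `z`.
#' @export
sim_helix_structure <- function(n_res = 100, chain = "A", rise = 1.5,
                                twist_deg = 100, radius = 2.3) {
  assert_number(n_res, "n_res", positive = TRUE)
  i <- seq_len(n_res)
  theta <- (i - 1) * twist_deg * pi / 180
  tibble(chain = chain, resno = i,
         x = radius * cos(theta), y = radius * sin(theta),
         z = (i - 1) * rise)
}

#' Synthetic per-residue variant counts with an optional depletion
#' cluster
#'
#' Expected counts are constant across residues; observed counts are
#' Poisson draws around them, with the observed missense mean suppressed
#' by `depletion_strength` inside `depletion_range` (a contiguous run of
#' residue indices).  With `noise = FALSE` the observed counts equal
#' their means exactly, giving a flat tolerance map at 1 outside the
#' cluster.
#'
#' @param coords Residue coordinates (defines chain/resno keys).
#' @param exp_mis,exp_syn Expected per-residue counts.
#' @param depletion_range Optional `c(first, last)` residue indices.
#' @param depletion_strength Multiplier on observed missense inside the
#'   cluster (0 = complete depletion).
#' @param noise Draw Poisson counts (TRUE) or use exact means (FALSE).
#' @param seed Integer seed.
#' @return A counts tibble for [mtr3d_map()].
#' @export
sim_variant_counts <- function(coords, exp_mis = 30, exp_syn = 10,
                               depletion_range = NULL,
                               depletion_strength = 0.2,
                               noise = TRUE, seed = NULL) {
  assert_columns(coords, c("chain", "resno"))
  n <- nrow(coords)
  mis_mean <- rep(exp_mis, n)
  if (!is.null(depletion_range)) {
    inside <- coords$resno >= depletion_range[1] &
      coords$resno <= depletion_range[2]
    mis_mean[inside] <- mis_mean[inside] * depletion_strength
  }
  with_sim_seed(seed, {
    tibble(chain = coords$chain, resno = coords$resno,
           obs_mis = if (noise) rpois(n, mis_mean) else mis_mean,
           obs_syn = if (noise) rpois(n, exp_syn) else rep(exp_syn, n),
           exp_mis = exp_mis, exp_syn = exp_syn)
  })
}

#' Plot a residue tolerance map
#'
#' @param map A tibble from [mtr3d_map()].
#' @return A ggplot raster of tolerance along the chain(s).
#' @export
plot_mtr3d <- function(map) {
  assert_columns(map, c("chain", "resno", "mtr"))
  ggplot2::ggplot(map, ggplot2::aes(.data$resno, .data$chain,
                                    fill = .data$mtr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "3D tolerance") +
    ggplot2::labs(x = "Residue", y = "Chain") +
    ggplot2::theme_minimal()
}
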