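#' @title Simulation studies of co-contraction index behaviour
#' @description Four studies characterize how the six indices behave and
#'   relate: constant-signal surfaces and slices (the indices as functions of
#'   two scalar amplitudes), a correlation study over thousands of random
#'   synthetic pairs that tests the shape / amplitude / temporal grouping,
#'   and the scenario experiments probing amplitude normalization,
#'   cross-index comparability, and sensitivity to amplitude versus shape.
#' @name experiments
NULL

#' Compute all indices over a batch of EMG pairs
#'
#' @param pairs List of [emg_pair()] objects (e.g. from [gen_batch()]).
#' @param threshold Activation threshold for the temporal index.
#' @return A tibble in long format: `pair_id`, `index`, `group`, `value`,
#'   `defined`. Undefined values are kept as `NA` with `defined = FALSE`.
#' @export
cci_batch <- function(pairs, threshold = 0.1) {
  tabs <- lapply(seq_along(pairs), function(i) {
    tab <- cci_all(pairs[[i]], threshold = threshold)
    tab$pair_id <- i
    tab
  })
  dplyr::relocate(dplyr::bind_rows(tabs), "pair_id")
}

cci_wide <- function(long) {
  tidyr::pivot_wider(long[c("pair_id", "index", "value")],
                     names_from = "index", values_from = "value")
}

#' Correlation study: does the index grouping hold up?
#'
#' Generates equal-sized batches of sinusoid, first-order and second-order
#' polynomial pairs (3 x `n_per_family` pairs in total), computes all six
#' indices for each pair, and quantifies every pairwise relationship between
#' indices with Chatterjee's coefficient. Pairs on which an index is
#' undefined (Thoroughman-Shadmehr on identical signals, ratio indices on
#' silent pairs) are excluded listwise per coefficient. Stronger
#' within-category than between-category coefficients support the
#' shape-based / amplitude-driven / temporal classification.
#'
#' @param n_per_family Pairs per signal family (study size 1000).
#' @param n_samples Samples per signal (default 100).
#' @param threshold Activation threshold for the temporal index (default
#'   0.1; used only by that index — any nonzero amplitude counts as active
#'   for the others).
#' @param seed Integer seed controlling generation and the random
#'   tie-breaking inside the coefficient; same seed, same tables.
#' @return A list with elements `cci` (long per-pair value table, with a
#'   `family` column), `xi` (30-row directional coefficient table from
#'   [xi_table()]), `xi_max` (15-row per-unordered-pair maxima from
#'   [xi_pair_max()]), and `config`.
#' @export
correlation_study <- function(n_per_family = 1000, n_samples = 100,
                              threshold = 0.1, seed = 1) {
  stopifnot(n_per_family >= 1)
  config <- list(study = "correlation", n_per_family = n_per_family,
                 n_samples = n_samples, threshold = threshold, seed = seed)
  with_seed(seed, {
    families <- c("sinusoid", "poly1", "poly2")
    long <- dplyr::bind_rows(lapply(families, function(fam) {
      batch <- gen_batch(fam, n_per_family, n_samples)
      tab <- cci_batch(batch, threshold = threshold)
      tab$family <- fam
      tab
    }))
    long$pair_id <- rep(seq_len(3 * n_per_family), each = 6)
    wide <- cci_wide(long)
    xi <- xi_table(wide[cci_ids()])
    list(cci = long, xi = xi, xi_max = xi_pair_max(xi), config = config)
  })
}

#' Headline statistics of a correlation study
#'
#' Reduces the per-unordered-pair coefficient maxima to the quantities the
#' classification claim rests on: the weakest link inside the shape-based
#' trio, the amplitude-driven pair's coefficient, and the weakest link among
#' all ten pairs of non-temporal indices.
#'
#' @param xi_max Tibble from [xi_pair_max()] (element `xi_max` of
#'   [correlation_study()]).
#' @return A tibble with columns `stat` (`min_shape`, `xi_amplitude`,
#'   `min_nontemporal`) and `xi`.
#' @export
correlation_summary <- function(xi_max) {
  grp <- cci_groups()
  ga <- grp[xi_max$index_a]
  gb <- grp[xi_max$index_b]
  shape <- ga == "shape" & gb == "shape"
  amp <- ga == "amplitude" & gb == "amplitude"
  nontemp <- ga != "temporal" & gb != "temporal"
  tibble::tibble(
    stat = c("min_shape", "xi_amplitude", "min_nontemporal"),
    xi = c(min(xi_max$xi[shape]), xi_max$xi[amp],
           min(xi_max$xi[nontemp])))
}

constant_pair <- function(e1, e2) emg_pair(rep(e1, 2), rep(e2, 2))

#' Index surfaces over constant-signal pairs
#'
#' Evaluates the five non-temporal indices on all pairs of constant signals
#' `(e1, e2)` over a uniform grid on \[0, 1\]^2. Under constant signals every
#' index reduces to a closed form in the two amplitudes, so the surfaces
#' display each index's full range of behaviour: shape-based surfaces carry a
#' high ridge along the diagonal (similar signals, any amplitude), while the
#' amplitude-driven surfaces peak only at (1, 1). The temporal index is
#' excluded: it does not vary with amplitude beyond the threshold crossing.
#' The Thoroughman-Shadmehr index is undefined on the exact diagonal and is
#' reported there as `NA`, not infinity.
#'
#' @param resolution Grid points per axis (default 101).
#' @return A tibble with columns `index`, `e1`, `e2`, `value`, `defined`.
#' @export
surface_study <- function(resolution = 101) {
  stopifnot(resolution >= 2)
  e <- seq(0, 1, length.out = resolution)
  grid <- expand.grid(e1 = e, e2 = e)
  fns <- list(SR = cci_sr, FW = cci_fw, TS = cci_ts, UF = cci_uf, R = cci_r)
  out <- lapply(names(fns), function(id) {
    res <- lapply(seq_len(nrow(grid)),
                  function(i) fns[[id]](constant_pair(grid$e1[i], grid$e2[i])))
    tibble::tibble(index = id, e1 = grid$e1, e2 = grid$e2,
                   value = vapply(res, function(r) r$value, numeric(1)),
                   defined = vapply(res, function(r) r$defined, logical(1)))
  })
  dplyr::bind_rows(out)
}

#' Shape-based index slice at fixed higher envelope
#'
#' Tabulates the three shape-based indices for constant pairs
#' `(e_low, e_high)` with `e_high` fixed and `e_low` swept over
#' `[0, e_high)`. With `x = e_low / e_high` the closed forms are `x` (simple
#' ratio, linear), `2x / (1 + x)` (Falconer-Winter, concave) and
#' `x / (1 - x)` (Thoroughman-Shadmehr, asymptotic): all increase with the
#' lower envelope but at very different rates, so identical inputs yield
#' different co-contraction values even within the shape-based category.
#'
#' @param e_high Fixed higher amplitude, in (0, 1\].
#' @param resolution Number of `e_low` values (default 101), uniformly
#'   spaced on `[0, e_high)`.
#' @return A tibble with columns `e_low`, `SR`, `FW`, `TS`.
#' @export
slice_study <- function(e_high = 1, resolution = 101) {
  stopifnot(e_high > 0, e_high <= 1, resolution >= 2)
  e_low <- seq(0, e_high, length.out = resolution + 1)[seq_len(resolution)]
  vals <- lapply(e_low, function(x) {
    p <- constant_pair(x, e_high)
    c(SR = cci_sr(p)$value, FW = cci_fw(p)$value, TS = cci_ts(p)$value)
  })
  m <- do.call(rbind, vals)
  tibble::tibble(e_low = e_low, SR = m[, "SR"], FW = m[, "FW"],
                 TS = m[, "TS"])
}

scenario_study <- function(cases, threshold = 0.1, n_samples = 100) {
  dplyr::bind_rows(lapply(seq_len(nrow(cases)), function(i) {
    pair <- gen_scenario(cases$scenario[i], n_samples = n_samples,
                         peak = cases$peak[i])
    tab <- cci_all(pair, threshold = threshold)
    dplyr::bind_cols(cases[i, ], tab)
  }))
}

#' Amplitude-normalization study
#'
#' Emulates three amplitude-normalization conditions by rescaling EMG2's
#' peak to 1.4 (non-normalized), 1.0 (within-task maximum) and 0.6 (MVC or
#' M-wave reference) while EMG1 stays fixed, under two scenario geometries:
#' `norm_A`, where rescaling changes both the overlap (lower envelope) and
#' the total activity, and `norm_B`, where EMG2 stays the higher envelope
#' throughout so only the total changes. Amplitude-driven indices fall with
#' the peak in `norm_A`; shape-based indices rise as the peak falls in
#' `norm_B` (their denominator shrinks while the overlap is untouched).
#'
#' @param threshold Activation threshold for the temporal index.
#' @param n_samples Samples per signal (default 100).
#' @return A tibble: `scenario`, `peak`, `index`, `group`, `value`,
#'   `defined` (2 scenarios x 3 peaks x 6 indices = 36 rows).
#' @export
normalization_study <- function(threshold = 0.1, n_samples = 100) {
  cases <- tidyr::expand_grid(scenario = c("norm_A", "norm_B"),
                              peak = c(1.4, 1.0, 0.6))
  scenario_study(cases, threshold = threshold, n_samples = n_samples)
}

#' Cross-index comparability study
#'
#' Runs the three canonical overlap scenarios — none, complete, partial —
#' through all six indices. With no overlap every index returns zero; under
#' complete maximal overlap the indices all flag "full" co-contraction but
#' on different scales (1 for the ratio indices and the mean overlap, 100
#' percent for the temporal index, 2 for Rudolph, undefined for
#' Thoroughman-Shadmehr), and under partial overlap the values spread out
#' across indices — absolute values from different indices are not
#' comparable.
#'
#' @inheritParams normalization_study
#' @return A tibble: `scenario`, `peak`, `index`, `group`, `value`,
#'   `defined` (3 scenarios x 6 indices = 18 rows).
#' @export
comparability_study <- function(threshold = 0.1, n_samples = 100) {
  cases <- tibble::tibble(
    scenario = c("no_overlap", "complete_overlap", "partial_overlap"),
    peak = 1)
  scenario_study(cases, threshold = threshold, n_samples = n_samples)
}

#' Amplitude-sensitivity study
#'
#' Runs the same waveform pair at two amplitude scales (conditions akin to
#' level versus uneven-terrain walking, where amplitude rises but shape
#' barely changes). Shape-based indices return identical values in both
#' conditions; amplitude-driven indices scale with amplitude, and the
#' temporal index grows with the longer supra-threshold overlap — so only
#' amplitude-sensitive indices can detect this kind of difference.
#'
#' @inheritParams normalization_study
#' @return A tibble: `scenario`, `peak`, `index`, `group`, `value`,
#'   `defined` (2 conditions x 6 indices = 12 rows).
#' @export
sensitivity_study <- function(threshold = 0.1, n_samples = 100) {
  cases <- tibble::tibble(
    scenario = c("sensitivity_low", "sensitivity_high"),
    peak = c(0.5, 1))
  scenario_study(cases, threshold = threshold, n_samples = n_samples)
}
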