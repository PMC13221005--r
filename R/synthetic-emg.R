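#' @title Synthetic EMG generation
#' @description Two families of inputs drive the simulation studies: random
#'   signal families (sinusoids and low-order polynomials, rectified and
#'   rescaled into normalized amplitude units) used for the index correlation
#'   study, and deterministic piecewise-linear scenario signals used for the
#'   normalization, comparability and sensitivity experiments. Neither family
#'   attempts physiological realism (no motor-unit model, no noise spectrum);
#'   they span a wide range of waveform shapes and overlap patterns under
#'   exact control.
#' @name synthetic_emg
NULL

# evaluate with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Rectify a signal and rescale it into [0, 1]
#'
#' Full-wave rectification (absolute value) removes negative excursions, the
#' standard EMG convention. A signal whose maximum then exceeds 1 is divided
#' by that maximum; signals already within \[0, 1\] are left untouched, and
#' no minimum is subtracted, so zero-activity samples stay exactly zero.
#'
#' @param x Numeric vector of finite samples.
#' @return An [emg_signal()] with all samples in \[0, 1\].
#' @examples
#' rectify_rescale(c(0, 2, -1))  # 0, 1, 0.5
#' @export
rectify_rescale <- function(x) {
  x <- abs(as.numeric(x))
  m <- max(x)
  if (m > 1) x <- x / m
  emg_signal(x)
}

#' Random sinusoid EMG pair
#'
#' Draws `EMG1 = c1*sin(c2*(t - c3)) + c4` and
#' `EMG2 = c5*cos(c6*(t - c7)) + c8` over 100 samples on \[0, 2*pi\], with
#' the frequency coefficients `c2, c6 ~ U(0, 10)` and all other coefficients
#' `~ U(0, 1)`, then rectifies and rescales each signal into \[0, 1\]. With
#' frequencies up to 10 the window spans anything from a fraction of a cycle
#' to ten full cycles, giving a wide variety of waveform shapes.
#'
#' Draws come from R's current RNG stream; seed via [gen_batch()] or
#' `set.seed()` for reproducibility.
#'
#' @param n_samples Samples per signal (default 100).
#' @param coefs Optional numeric vector `c(c1, ..., c8)` overriding the
#'   random draw (used to pin down closed-form cases).
#' @return An [emg_pair()].
#' @export
gen_sinusoid_pair <- function(n_samples = 100, coefs = NULL) {
  if (is.null(coefs)) {
    coefs <- stats::runif(8)
    coefs[c(2, 6)] <- stats::runif(2, 0, 10)
  }
  stopifnot(length(coefs) == 8)
  t <- seq(0, 2 * pi, length.out = n_samples)
  e1 <- coefs[1] * sin(coefs[2] * (t - coefs[3])) + coefs[4]
  e2 <- coefs[5] * cos(coefs[6] * (t - coefs[7])) + coefs[8]
  emg_pair(rectify_rescale(e1), rectify_rescale(e2))
}

#' Random polynomial EMG pair
#'
#' Each signal is a first- or second-order polynomial in `t` over 100 samples
#' on \[0, 1\], with slope/curvature coefficients `~ U(-1, 1)` and intercept
#' `~ U(0, 1)`, rectified and rescaled into \[0, 1\].
#'
#' @param order Polynomial order, 1 or 2.
#' @inheritParams gen_sinusoid_pair
#' @param coefs Optional list with elements `emg1` and `emg2`, each a numeric
#'   vector `c(intercept, b1[, b2])`, overriding the random draw.
#' @return An [emg_pair()].
#' @export
gen_poly_pair <- function(order, n_samples = 100, coefs = NULL) {
  stopifnot(order %in% c(1, 2))
  if (is.null(coefs)) {
    coefs <- list(emg1 = c(stats::runif(1), stats::runif(order, -1, 1)),
                  emg2 = c(stats::runif(1), stats::runif(order, -1, 1)))
  }
  t <- seq(0, 1, length.out = n_samples)
  eval_poly <- function(cf) {
    drop(cbind(1, stats::poly(t, degree = length(cf) - 1, raw = TRUE)) %*% cf)
  }
  emg_pair(rectify_rescale(eval_poly(coefs$emg1)),
           rectify_rescale(eval_poly(coefs$emg2)))
}

#' Generate a reproducible batch of random EMG pairs
#'
#' @param family One of `"sinusoid"`, `"poly1"`, `"poly2"`.
#' @param n_pairs Number of pairs to generate.
#' @param n_samples Samples per signal (default 100).
#' @param seed Optional integer; when given, the batch is drawn from a
#'   temporary RNG stream seeded with it (the caller's stream is untouched)
#'   so the same spec always yields the same batch.
#' @return A list of [emg_pair()] objects, with the generation spec attached
#'   as attribute `"spec"`.
#' @examples
#' batch <- gen_batch("sinusoid", 5, seed = 1)
#' @export
gen_batch <- function(family = c("sinusoid", "poly1", "poly2"), n_pairs,
                      n_samples = 100, seed = NULL) {
  family <- match.arg(family)
  stopifnot(n_pairs >= 1, n_samples >= 2)
  gen <- switch(family,
    sinusoid = function() gen_sinusoid_pair(n_samples),
    poly1    = function() gen_poly_pair(1, n_samples),
    poly2    = function() gen_poly_pair(2, n_samples))
  pairs <- with_seed(seed, replicate(n_pairs, gen(), simplify = FALSE))
  attr(pairs, "spec") <- list(family = family, n_pairs = n_pairs,
                              n_samples = n_samples, seed = seed)
  pairs
}

# piecewise-linear waveform over t in [0, 1]
pwl <- function(xs, ys, n_samples) {
  stats::approx(xs, ys, xout = seq(0, 1, length.out = n_samples))$y
}

scenario_default_peak <- c(no_overlap = 1, complete_overlap = 1,
                           partial_overlap = 1, norm_A = 1, norm_B = 1,
                           sensitivity_low = 0.5, sensitivity_high = 1)

#' Deterministic piecewise-linear scenario signals
#'
#' Generates the controlled EMG pairs behind the scenario experiments, each
#' a piecewise-linear waveform over `n_samples` uniformly spaced points:
#'
#' \describe{
#'   \item{`no_overlap`}{two temporally disjoint triangular bursts; the
#'     pointwise minimum is identically zero.}
#'   \item{`complete_overlap`}{both muscles constant at `peak` throughout
#'     (maximal identical activation).}
#'   \item{`partial_overlap`}{two triangular bursts that overlap in the
#'     middle of the window.}
#'   \item{`norm_A`}{EMG1 a fixed unit triangle; EMG2 a ramp rising to
#'     `peak`, so EMG2 is the lower envelope for roughly the first two
#'     thirds of the window. Rescaling EMG2 changes both the overlap and
#'     the total activity — the case where amplitude normalization hits
#'     amplitude-driven indices hardest.}
#'   \item{`norm_B`}{EMG1 a fixed low triangle; EMG2 a trapezoid scaled by
#'     `peak` that stays above EMG1 for any `peak >= 0.6`, so rescaling
#'     EMG2 changes only the higher envelope / total activity — the case
#'     where shape-based indices move and amplitude-driven ones barely do.}
#'   \item{`sensitivity_low` / `sensitivity_high`}{the same two largely
#'     overlapping triangular bursts at different amplitude scales
#'     (defaults 0.5 and 1.0): waveform shape identical, amplitude and
#'     supra-threshold duration different.}
#' }
#'
#' The waveform geometry reconstructs the qualitative structure of these
#' conditions (disjoint / identical / partially overlapping bursts and their
#' amplitude-scaled variants); conclusions drawn from the scenarios rest only
#' on geometry-independent properties (zeros, maxima, invariances,
#' monotonicities).
#'
#' @param scenario_id One of `no_overlap`, `complete_overlap`,
#'   `partial_overlap`, `norm_A`, `norm_B`, `sensitivity_low`,
#'   `sensitivity_high`.
#' @param n_samples Samples per signal (default 100).
#' @param peak Amplitude scale; for the `norm_*` scenarios the exact maximum
#'   of EMG2 (study values 0.6 / 1.0 / 1.4). Defaults to the scenario's
#'   standard value (0.5 for `sensitivity_low`, 1 otherwise).
#' @return An [emg_pair()]; signals lie in `[0, peak]`.
#' @examples
#' gen_scenario("complete_overlap")
#' @export
gen_scenario <- function(scenario_id, n_samples = 100, peak = NULL) {
  ids <- names(scenario_default_peak)
  if (!scenario_id %in% ids) {
    stop("unknown scenario_id '", scenario_id, "'; expected one of: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  if (is.null(peak)) peak <- unname(scenario_default_peak[scenario_id])
  stopifnot(is.numeric(peak), length(peak) == 1, peak > 0)
  n <- n_samples

  pair <- switch(scenario_id,
    no_overlap = emg_pair(
      peak * pwl(c(0, 0.225, 0.45, 1), c(0, 1, 0, 0), n),
      peak * pwl(c(0, 0.55, 0.775, 1), c(0, 0, 1, 0), n)),
    complete_overlap = emg_pair(rep(peak, n), rep(peak, n)),
    partial_overlap = emg_pair(
      peak * pwl(c(0, 0.35, 0.7, 1), c(0, 1, 0, 0), n),
      peak * pwl(c(0, 0.3, 0.65, 1), c(0, 0, 1, 0), n)),
    norm_A = emg_pair(
      pwl(c(0, 0.5, 1), c(0, 1, 0), n),
      peak * pwl(c(0, 1), c(0, 1), n)),
    norm_B = emg_pair(
      pwl(c(0, 0.2, 0.5, 0.8, 1), c(0, 0, 0.3, 0, 0), n),
      peak * pwl(c(0, 0.3, 0.7, 1), c(0, 1, 1, 0), n)),
    sensitivity_low = ,
    sensitivity_high = emg_pair(
      peak * pwl(c(0, 0.1, 0.5, 0.9, 1), c(0, 0, 1, 0, 0), n),
      peak * pwl(c(0, 0.15, 0.55, 0.95, 1), c(0, 0, 1, 0, 0), n))
  )
  attr(pair, "scenario") <- list(scenario_id = scenario_id,
                                 n_samples = n_samples, peak = peak)
  pair
}
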