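#' @title Co-contraction index calculators
#' @description Six scalar summaries of the degree of simultaneous activation
#'   in an agonist-antagonist EMG pair. All integrals are computed as sample
#'   means over the observation window, i.e. a Riemann sum with the window
#'   duration normalized to 1. This convention cancels out of the shape-based
#'   ratios, matches the explicit divide-by-N of the Unnithan-Frost formula,
#'   and makes the Rudolph index attain its theoretical maximum of 2 for
#'   signals bounded by 1.
#' @name cci
NULL

cci_result <- function(index, value, defined = TRUE, series = NULL,
                       note = NULL) {
  structure(list(index = index, value = value, defined = defined,
                 series = series, note = note),
            class = "cci_result")
}

#' @export
print.cci_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<cci_result> %s = %s\n", x$index, format(x$value)))
  } else {
    cat(sprintf("<cci_result> %s undefined (%s)\n", x$index,
                x$note %||% "not computable"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simple ratio co-contraction index
#'
#' The ratio of the integrated lower envelope to the integrated higher
#' envelope, i.e. antagonist over agonist activity without designating which
#' muscle is which. Values lie in \[0, 1\]: 0 for no overlap, 1 for identical
#' signals regardless of their amplitude (shape-based).
#'
#' @param pair An [emg_pair()].
#' @return A `cci_result`. `defined` is `FALSE` when both signals are
#'   identically zero (no activity to form a ratio of).
#' @examples
#' cci_sr(emg_pair(rep(0.5, 10), rep(1, 10)))  # 0.5
#' @export
cci_sr <- function(pair) {
  d <- decompose(pair)
  denom <- mean(d$high)
  if (denom == 0) {
    return(cci_result("SR", NA_real_, defined = FALSE, note = "no activity"))
  }
  cci_result("SR", mean(d$low) / denom)
}

#' Falconer-Winter co-contraction index
#'
#' Twice the integrated overlap (lower envelope) divided by the integrated
#' total activity of both muscles. The factor of two bounds the index to
#' \[0, 1\]; it equals 1 exactly when the two signals are identical
#' (shape-based).
#'
#' @inheritParams cci_sr
#' @return A `cci_result`; `defined = FALSE` for an all-zero pair.
#' @examples
#' cci_fw(emg_pair(rep(0.5, 10), rep(1, 10)))  # 2*0.5/1.5 = 2/3
#' @export
cci_fw <- function(pair) {
  pair <- as_emg_pair(pair)
  d <- decompose(pair)
  total <- mean(as.numeric(pair$emg1) + as.numeric(pair$emg2))
  if (total == 0) {
    return(cci_result("FW", NA_real_, defined = FALSE, note = "no activity"))
  }
  cci_result("FW", 2 * mean(d$low) / total)
}

#' Thoroughman-Shadmehr co-contraction index
#'
#' The mean "wasted contraction" (lower envelope) divided by the maximum
#' "effective contraction" (pointwise difference between the envelopes). The
#' index has no upper bound: as the two signals approach each other the
#' denominator shrinks and the value grows without limit, and for identical
#' signals the maximum effective contraction is zero and the index is
#' undefined. Values are returned as computed, however large.
#'
#' @inheritParams cci_sr
#' @return A `cci_result`; `defined = FALSE` when the two signals are
#'   identical (zero maximum effective contraction).
#' @examples
#' cci_ts(emg_pair(rep(0.5, 10), rep(1, 10)))  # mean(0.5)/max(0.5) = 1
#' @export
cci_ts <- function(pair) {
  d <- decompose(pair)
  effective_max <- max(d$high - d$low)
  if (effective_max == 0) {
    return(cci_result("TS", NA_real_, defined = FALSE,
                      note = "undefined (zero effective contraction)"))
  }
  cci_result("TS", mean(d$low) / effective_max)
}

#' Unnithan-Frost co-contraction index
#'
#' The integrated overlap divided by the number of samples: the mean of the
#' lower envelope, i.e. the average amplitude of the overlap between the two
#' signals. Requires high activation in both muscles to be large
#' (amplitude-driven); for signals bounded by 1 its maximum is 1.
#'
#' @inheritParams cci_sr
#' @return A `cci_result`; always defined.
#' @examples
#' cci_uf(emg_pair(rep(0.5, 10), rep(1, 10)))  # 0.5
#' @export
cci_uf <- function(pair) {
  d <- decompose(pair)
  cci_result("UF", mean(d$low))
}

#' Rudolph co-contraction time-series
#'
#' At each sample, the ratio of the less to the more active muscle multiplied
#' by the summed activity of both. Samples where both muscles are silent
#' (high envelope exactly 0) contribute 0: no activity means no
#' co-contraction, and the numerator vanishes there anyway.
#'
#' @inheritParams cci_sr
#' @return Numeric vector of per-sample values, length `pair$n`.
#' @examples
#' cci_r_series(emg_pair(rep(0.5, 3), rep(1, 3)))  # 0.75 at every sample
#' @export
cci_r_series <- function(pair) {
  pair <- as_emg_pair(pair)
  d <- decompose(pair)
  total <- as.numeric(pair$emg1) + as.numeric(pair$emg2)
  series <- numeric(pair$n)
  active <- d$high > 0
  series[active] <- (d$low[active] / d$high[active]) * total[active]
  series
}

#' Rudolph co-contraction index
#'
#' The Rudolph time-series reduced to a scalar by integration over the
#' unit-normalized window, which coincides with the mean of the series. The
#' sum is deliberately not offered as a reduction: it grows with the number of
#' samples and inflates co-contraction estimates. For signals bounded by 1
#' the maximum is 2, attained when both muscles are maximally active
#' throughout (amplitude-driven).
#'
#' @inheritParams cci_sr
#' @return A `cci_result` with the per-sample series retained in `$series`;
#'   always defined.
#' @examples
#' cci_r(emg_pair(rep(1, 10), rep(1, 10)))  # 2
#' @export
cci_r <- function(pair) {
  series <- cci_r_series(pair)
  cci_result("R", mean(series), series = series)
}

#' Temporal co-contraction index
#'
#' The percentage of the observation window during which both muscles are
#' simultaneously active, with activity defined by a fixed amplitude
#' threshold (default 0.1 in normalized units). Insensitive to amplitude and
#' shape beyond the threshold crossings; the total time counts all samples in
#' the window.
#'
#' @inheritParams cci_sr
#' @param threshold Activation threshold (normalized amplitude, `>= 0`); a
#'   muscle is active at a sample when its amplitude is at least this value.
#' @return A `cci_result` in percent (0-100); always defined.
#' @examples
#' cci_t(emg_pair(rep(1, 10), c(rep(1, 4), rep(0, 6))))  # 40
#' @export
cci_t <- function(pair, threshold = 0.1) {
  pair <- as_emg_pair(pair)
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  both_active <- as.numeric(pair$emg1) >= threshold &
    as.numeric(pair$emg2) >= threshold
  cci_result("T", 100 * sum(both_active) / pair$n)
}

#' Index identifiers and category labels
#'
#' The six indices fall into three behavioural categories: shape-based
#' indices (SR, FW, TS) respond to waveform similarity regardless of
#' amplitude, amplitude-driven indices (UF, R) require high activation in
#' both muscles, and the temporal index (T) measures overlap duration only.
#'
#' @return `cci_ids()`: character vector of the six identifiers.
#'   `cci_groups()`: named character vector mapping identifier to category.
#' @export
cci_ids <- function() c("SR", "FW", "TS", "UF", "R", "T")

#' @rdname cci_ids
#' @export
cci_groups <- function() {
  c(SR = "shape", FW = "shape", TS = "shape",
    UF = "amplitude", R = "amplitude", T = "temporal")
}

#' Compute all six co-contraction indices for one pair
#'
#' @inheritParams cci_t
#' @return A tibble with one row per index: columns `index`, `group`,
#'   `value` (`NA` when undefined) and `defined`. Undefined results (the
#'   Thoroughman-Shadmehr index on identical signals, ratio indices on an
#'   all-zero pair) are carried with `defined = FALSE`, never dropped.
#' @examples
#' cci_all(emg_pair(rep(1, 10), rep(1, 10)))
#' @export
cci_all <- function(pair, threshold = 0.1) {
  pair <- as_emg_pair(pair)
  results <- list(cci_sr(pair), cci_fw(pair), cci_ts(pair),
                  cci_uf(pair), cci_r(pair), cci_t(pair, threshold))
  tibble::tibble(
    index   = vapply(results, function(r) r$index, character(1)),
    group   = unname(cci_groups()[vapply(results, function(r) r$index,
                                         character(1))]),
    value   = vapply(results, function(r) r$value, numeric(1)),
    defined = vapply(results, function(r) r$defined, logical(1))
  )
}
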