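#' Construct a rectified EMG envelope signal
#'
#' An `emg_signal` is one uniformly sampled, non-negative EMG envelope in
#' dimensionless (amplitude-normalized) units. Co-contraction indices assume
#' their inputs have already been rectified and enveloped; raw EMG must be
#' preprocessed upstream.
#'
#' @param samples Numeric vector of amplitudes; all values must be finite and
#'   non-negative, with at least two samples.
#' @return An object of class `emg_signal`: a numeric vector with the class
#'   attribute set.
#' @examples
#' emg_signal(c(0, 0.4, 0.8, 0.4, 0))
#' @export
emg_signal <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    stop("an EMG signal needs at least 2 samples, got ", length(samples),
         call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    bad <- which(!is.finite(samples))[1]
    stop("non-finite amplitude at sample ", bad,
         "; EMG envelopes must be finite", call. = FALSE)
  }
  if (any(samples < 0)) {
    bad <- which(samples < 0)[1]
    stop("negative amplitude ", format(samples[bad]), " at sample ", bad,
         "; rectify the signal before computing co-contraction", call. = FALSE)
  }
  structure(samples, class = "emg_signal")
}

#' Construct an agonist-antagonist EMG pair
#'
#' Bundles two EMG envelopes recorded from an agonist-antagonist muscle pair
#' on a shared, uniformly sampled time base. All index calculators operate on
#' this container. Neither signal needs to be designated the agonist: every
#' index here is symmetric in the two inputs.
#'
#' @param emg1,emg2 Numeric vectors (or `emg_signal` objects) of equal length.
#' @return An object of class `emg_pair` with elements `emg1`, `emg2`
#'   (both `emg_signal`) and `n` (shared sample count).
#' @examples
#' p <- emg_pair(c(0.2, 0.9, 0.4), c(0.3, 0.1, 0.4))
#' p$n
#' @export
emg_pair <- function(emg1, emg2) {
  e1 <- emg_signal(unclass(emg1))
  e2 <- emg_signal(unclass(emg2))
  if (length(e1) != length(e2)) {
    stop("EMG signals must share a time base: lengths ", length(e1), " and ",
         length(e2), call. = FALSE)
  }
  structure(list(emg1 = e1, emg2 = e2, n = length(e1)), class = "emg_pair")
}

#' @export
print.emg_pair <- function(x, ...) {
  cat("<emg_pair> n =", x$n,
      " max1 =", format(max(x$emg1), digits = 4),
      " max2 =", format(max(x$emg2), digits = 4), "\n")
  invisible(x)
}

as_emg_pair <- function(pair) {
  if (inherits(pair, "emg_pair")) pair else emg_pair(pair[[1]], pair[[2]])
}

#' Pointwise low/high decomposition of an EMG pair
#'
#' At each time sample, the smaller of the two amplitudes is EMG_low and the
#' larger is EMG_high. Every index is a functional of this decomposition:
#' EMG_low is the "wasted" (cancelled) contraction and EMG_high - EMG_low the
#' "effective" contraction. At ties the common value is assigned to both, so
#' the effective contraction is exactly zero there.
#'
#' @param pair An [emg_pair()].
#' @return A list with components `low` and `high`, numeric vectors of
#'   length `pair$n` satisfying `low <= high` everywhere.
#' @examples
#' decompose(emg_pair(c(1, 0), c(0, 1)))
#' @export
decompose <- function(pair) {
  pair <- as_emg_pair(pair)
  list(low  = pmin(as.numeric(pair$emg1), as.numeric(pair$emg2)),
       high = pmax(as.numeric(pair$emg1), as.numeric(pair$emg2)))
}

#' Scale both signals of a pair by a common factor
#'
#' Joint amplitude scaling is the operation behind the normalization and
#' sensitivity experiments: shape-based indices are invariant under it while
#' amplitude-driven indices scale linearly.
#'
#' @param pair An [emg_pair()].
#' @param k Positive scale factor.
#' @return A new `emg_pair`.
#' @export
scale_pair <- function(pair, k) {
  pair <- as_emg_pair(pair)
  stopifnot(is.numeric(k), length(k) == 1, k > 0)
  emg_pair(as.numeric(pair$emg1) * k, as.numeric(pair$emg2) * k)
}
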