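#' Chatterjee's rank correlation coefficient
#'
#' A rank-based measure of the dependence of `y` on `x` that detects
#' nonlinear and nonmonotonic relationships, unlike Pearson's r (linear only)
#' or Spearman's rho (monotonic only). The estimator sorts the observations
#' by `x` and measures how wildly the ranks of `y` jump between neighbours:
#' for a noiseless functional relationship the sorted ranks move smoothly and
#' xi approaches 1; under independence xi concentrates around 0 (it can dip
#' slightly negative in finite samples, down to -0.5 asymptotically).
#'
#' With distinct `y` the ties-aware estimator reduces to
#' `1 - 3 * sum(|r[i+1] - r[i]|) / (n^2 - 1)` where `r` are the ranks of `y`
#' in `x`-sorted order. Ties among `x` are broken uniformly at random, as the
#' estimator requires; the draw comes from R's current RNG stream, so seed
#' before calling (or via the study functions' `seed` argument) for
#' reproducible results. The coefficient is directional: `xi(x, y)` measures
#' whether `y` is a function of `x` and generally differs from `xi(y, x)`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return An object of class `xi_estimate`: a list with `xi` (the
#'   coefficient), `n` (observations used) and `n_tied_x` (number of `x`
#'   values involved in ties, broken at random).
#' @examples
#' chatterjee_xi(1:5, 1:5)$xi  # 1 - 3*4/24 = 0.5
#' @export
chatterjee_xi <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have equal length, got ", length(x), " and ",
         length(y), call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  if (!all(keep)) stop("x and y must be finite", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations, got ", n, call. = FALSE)

  tied_x <- duplicated(x) | duplicated(x, fromLast = TRUE)
  tiebreak <- if (any(tied_x)) sample.int(n) else seq_len(n)
  ord <- order(x, tiebreak)
  ys <- y[ord]

  # r_i = #{j : y_j <= y_(i)},  l_i = #{j : y_j >= y_(i)}
  r <- as.numeric(rank(ys, ties.method = "max"))
  l <- n - as.numeric(rank(ys, ties.method = "min")) + 1
  denom <- 2 * sum(l * (n - l))
  if (denom == 0) {
    stop("degenerate: zero denominator (y is constant)", call. = FALSE)
  }
  xi <- 1 - n * sum(abs(diff(r))) / denom
  structure(list(xi = xi, n = n, n_tied_x = sum(tied_x)),
            class = "xi_estimate")
}

#' @export
print.xi_estimate <- function(x, ...) {
  cat(sprintf("<xi_estimate> xi = %s (n = %d)\n", format(x$xi), x$n))
  invisible(x)
}

#' Pairwise Chatterjee coefficients across index columns
#'
#' Computes the directional coefficient `xi(x -> y)` for every ordered pair
#' of columns of a wide value table (one row per EMG pair, one column per
#' co-contraction index). Rows where either column is `NA` — an undefined
#' index value, e.g. Thoroughman-Shadmehr on near-identical signals — are
#' excluded listwise from that coefficient only, and the exclusion count is
#' recorded.
#'
#' @param values A data frame or tibble of numeric columns; `NA` marks
#'   undefined values.
#' @return A tibble with one row per ordered column pair: `index_x`,
#'   `index_y`, `xi`, `n_used`, `n_excluded`.
#' @export
xi_table <- function(values) {
  values <- as.data.frame(values)
  ids <- names(values)
  pairs <- expand.grid(index_x = ids, index_y = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$index_x != pairs$index_y, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- values[[pairs$index_x[i]]]
    b <- values[[pairs$index_y[i]]]
    keep <- !is.na(a) & !is.na(b)
    est <- chatterjee_xi(a[keep], b[keep])
    tibble::tibble(index_x = pairs$index_x[i], index_y = pairs$index_y[i],
                   xi = est$xi, n_used = sum(keep),
                   n_excluded = sum(!keep))
  })
  dplyr::bind_rows(rows)
}

#' Symmetrize a directional xi table over unordered pairs
#'
#' The coefficient is directional, but headline claims about the strength of
#' association between two indices are evaluated on the stronger of the two
#' directions. Collapses the ordered-pair table to one row per unordered
#' pair, keeping the maximum of `xi(a -> b)` and `xi(b -> a)`.
#'
#' @param tab A tibble from [xi_table()].
#' @return A tibble with columns `index_a`, `index_b` (alphabetical order
#'   within pair), `xi` (max of the two directions), `n_used`, `n_excluded`.
#' @export
xi_pair_max <- function(tab) {
  tab <- dplyr::mutate(tab,
    index_a = pmin(.data$index_x, .data$index_y),
    index_b = pmax(.data$index_x, .data$index_y))
  dplyr::summarise(
    dplyr::group_by(tab, .data$index_a, .data$index_b),
    xi = max(.data$xi),
    n_used = .data$n_used[1],
    n_excluded = .data$n_excluded[1],
    .groups = "drop")
}
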