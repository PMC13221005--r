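# Independent brute-force implementations used as oracles. These deliberately
# avoid the package's code paths: explicit loops, no shared helpers.

brute_cci <- function(e1, e2, threshold = 0.1) {
  n <- length(e1)
  low <- high <- numeric(n)
  for (i in seq_len(n)) {
    low[i] <- if (e1[i] <= e2[i]) e1[i] else e2[i]
    high[i] <- if (e1[i] >= e2[i]) e1[i] else e2[i]
  }
  int <- function(x) sum(x) / length(x)  # unit-duration Riemann sum
  sr <- if (int(high) == 0) NA_real_ else int(low) / int(high)
  fw <- if (int(e1 + e2) == 0) NA_real_ else 2 * int(low) / int(e1 + e2)
  eff <- high - low
  ts <- if (max(eff) == 0) NA_real_ else int(low) / max(eff)
  uf <- int(low)
  r_series <- numeric(n)
  for (i in seq_len(n)) {
    r_series[i] <- if (high[i] == 0) 0 else
      (low[i] / high[i]) * (e1[i] + e2[i])
  }
  r <- int(r_series)
  overlap <- 0
  for (i in seq_len(n)) {
    if (e1[i] >= threshold && e2[i] >= threshold) overlap <- overlap + 1
  }
  tt <- 100 * overlap / n
  c(SR = sr, FW = fw, TS = ts, UF = uf, R = r, T = tt)
}

# Chatterjee xi by direct enumeration of the defining ranks; assumes x has no
# ties (so no random tie-breaking enters).
brute_xi <- function(x, y) {
  n <- length(x)
  stopifnot(!anyDuplicated(x))
  ord <- order(x)
  ys <- y[ord]
  r <- l <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(ys <= ys[i])
    l[i] <- sum(ys >= ys[i])
  }
  num <- 0
  for (i in seq_len(n - 1)) num <- num + abs(r[i + 1] - r[i])
  den <- 0
  for (i in seq_len(n)) den <- den + l[i] * (n - l[i])
  1 - n * num / (2 * den)
}

# all permutations of 1..n as rows of a matrix
perm_all <- function(n) {
  if (n == 1) return(matrix(1))
  p <- perm_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    left <- seq_len(pos - 1)
    right <- setdiff(seq_len(n - 1), left)
    cbind(p[, left, drop = FALSE], n, p[, right, drop = FALSE])
  }))
}

random_pair <- function(n) {
  ccindex::emg_pair(stats::runif(n), stats::runif(n))
}
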