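const_pair <- function(a, b, n = 10) emg_pair(rep(a, n), rep(b, n))
# one muscle active at a time: triangular bursts on disjoint supports
disjoint_pair <- function() {
  e1 <- c(0, 0.5, 1, 0.5, 0, 0, 0, 0, 0, 0)
  e2 <- c(0, 0, 0, 0, 0, 0, 0.5, 1, 0.5, 0)
  emg_pair(e1, e2)
}

test_that("simple ratio: identical, disjoint, constant-ratio and silent pairs", {
  expect_equal(cci_sr(const_pair(1, 1))$value, 1)
  expect_equal(cci_sr(disjoint_pair())$value, 0)
  expect_equal(cci_sr(const_pair(0.5, 1))$value, 0.5)
  silent <- cci_sr(const_pair(0, 0))
  expect_false(silent$defined)
  expect_match(silent$note, "no activity")
})

test_that("Falconer-Winter: identical signals give 1, disjoint give 0", {
  expect_equal(cci_fw(const_pair(1, 1))$value, 1)
  expect_equal(cci_fw(emg_pair(c(0.2, 0.7, 0.1), c(0.2, 0.7, 0.1)))$value, 1)
  expect_equal(cci_fw(disjoint_pair())$value, 0)
  expect_equal(cci_fw(const_pair(0.5, 1))$value, 2 * 0.5 / 1.5)
  expect_false(cci_fw(const_pair(0, 0))$defined)
})

test_that("Thoroughman-Shadmehr: undefined on identical signals, unbounded otherwise", {
  ident <- cci_ts(emg_pair(c(0.3, 0.8), c(0.3, 0.8)))
  expect_false(ident$defined)
  expect_match(ident$note, "zero effective contraction")
  expect_equal(cci_ts(const_pair(0.5, 1))$value, 1)
  # near-identical signals blow up but stay defined and finite
  near <- cci_ts(emg_pair(c(0.5, 0.5), c(0.5, 0.5 + 1e-9)))
  expect_true(near$defined)
  expect_gt(near$value, 1e8)
})

test_that("Unnithan-Frost is the mean of the lower envelope", {
  expect_equal(cci_uf(const_pair(1, 1))$value, 1)
  expect_equal(cci_uf(disjoint_pair())$value, 0)
  expect_equal(cci_uf(const_pair(0.5, 1))$value, 0.5)
  set.seed(7)
  p <- random_pair(50)
  expect_equal(cci_uf(p)$value, mean(decompose(p)$low))
})

test_that("Rudolph series and scalar: silent samples contribute zero, scalar is the mean", {
  expect_equal(cci_r_series(const_pair(1, 1, 5)), rep(2, 5))
  expect_equal(cci_r_series(emg_pair(rep(0, 5), runif(5))), rep(0, 5))
  expect_equal(cci_r_series(const_pair(0.5, 1, 3))[1], 0.75)
  expect_equal(cci_r(const_pair(1, 1))$value, 2)
  expect_equal(cci_r(const_pair(0.5, 1))$value, 0.75)
  expect_equal(cci_r(disjoint_pair())$value, 0)
  res <- cci_r(const_pair(0.5, 1, 4))
  expect_equal(res$series, rep(0.75, 4))
  # both muscles silent throughout: no activity, no co-contraction, still defined
  expect_equal(cci_r(const_pair(0, 0))$value, 0)
})

test_that("temporal index counts supra-threshold overlap as a percentage", {
  expect_equal(cci_t(const_pair(1, 1))$value, 100)
  expect_equal(cci_t(disjoint_pair())$value, 0)
  e1 <- rep(1, 100)
  e2 <- c(rep(0.5, 40), rep(0.05, 60))
  expect_equal(cci_t(emg_pair(e1, e2))$value, 40)
  # threshold is inclusive
  expect_equal(cci_t(const_pair(0.1, 0.1))$value, 100)
  expect_equal(cci_t(const_pair(0.3, 0.3), threshold = 0.5)$value, 0)
})

test_that("cci_all returns all six indices, carrying undefined results", {
  tab <- cci_all(const_pair(1, 1))
  expect_identical(sort(tab$index), sort(cci_ids()))
  expect_equal(tab$value[tab$index == "SR"], 1)
  expect_equal(tab$value[tab$index == "FW"], 1)
  expect_equal(tab$value[tab$index == "UF"], 1)
  expect_equal(tab$value[tab$index == "R"], 2)
  expect_equal(tab$value[tab$index == "T"], 100)
  expect_false(tab$defined[tab$index == "TS"])
  expect_true(is.na(tab$value[tab$index == "TS"]))

  zero <- cci_all(disjoint_pair())
  expect_equal(zero$value, rep(0, 6))
  expect_true(all(zero$defined))
})

test_that("shape-based indices are scale invariant; amplitude-driven scale linearly", {
  set.seed(101)
  for (rep in 1:10) {
    p <- random_pair(40)
    for (k in c(0.6, 1.4, 3.7)) {
      q <- scale_pair(p, k)
      expect_equal(cci_sr(q)$value, cci_sr(p)$value, tolerance = 1e-12)
      expect_equal(cci_fw(q)$value, cci_fw(p)$value, tolerance = 1e-12)
      expect_equal(cci_ts(q)$value, cci_ts(p)$value, tolerance = 1e-12)
      expect_equal(cci_uf(q)$value, k * cci_uf(p)$value, tolerance = 1e-12)
      expect_equal(cci_r(q)$value, k * cci_r(p)$value, tolerance = 1e-12)
    }
  }
})

test_that("temporal index is invariant under monotone transforms preserving crossings", {
  set.seed(17)
  base <- sample(c(0, 0.5, 1), 60, replace = TRUE)
  other <- sample(c(0, 0.5, 1), 60, replace = TRUE)
  p <- emg_pair(base, other)
  v0 <- cci_t(p)$value
  for (f in list(function(x) x^2, function(x) 0.8 * x + 0.01,
                 function(x) sqrt(x) * 0.9)) {
    expect_equal(cci_t(emg_pair(f(base), f(other)))$value, v0)
  }
})

test_that("index values respect their theoretical bounds on random pairs", {
  set.seed(23)
  for (rep in 1:25) {
    p <- random_pair(30)
    expect_gte(cci_sr(p)$value, 0); expect_lte(cci_sr(p)$value, 1)
    expect_gte(cci_fw(p)$value, 0); expect_lte(cci_fw(p)$value, 1)
    m <- max(decompose(p)$high)
    expect_gte(cci_uf(p)$value, 0); expect_lte(cci_uf(p)$value, m)
    expect_gte(cci_r(p)$value, 0); expect_lte(cci_r(p)$value, 2 * m)
    tv <- cci_t(p)$value
    expect_gte(tv, 0); expect_lte(tv, 100)
    expect_gte(cci_ts(p)$value, 0)
  }
})

test_that("constant-pair closed forms hold on a grid: x, 2x/(1+x), x/(1-x)", {
  for (x in seq(0, 0.99, by = 0.03)) {
    p <- const_pair(x, 1)
    expect_equal(cci_sr(p)$value, x, tolerance = 1e-12)
    expect_equal(cci_fw(p)$value, 2 * x / (1 + x), tolerance = 1e-12)
    expect_equal(cci_ts(p)$value, x / (1 - x), tolerance = 1e-12)
  }
})

test_that("TS equals UF whenever the maximum effective contraction is 1", {
  set.seed(31)
  for (rep in 1:10) {
    e1 <- runif(20)
    e2 <- runif(20)
    e1[5] <- 1; e2[5] <- 0   # pin max effective contraction to exactly 1
    p <- emg_pair(e1, e2)
    expect_equal(max(decompose(p)$high - decompose(p)$low), 1)
    expect_equal(cci_ts(p)$value, cci_uf(p)$value, tolerance = 1e-12)
  }
})

test_that("every index matches the brute-force oracle on small random pairs", {
  set.seed(53)
  for (rep in 1:30) {
    n <- sample(2:10, 1)
    e1 <- round(runif(n), 3)
    e2 <- round(runif(n), 3)
    expected <- brute_cci(e1, e2)
    got <- cci_all(emg_pair(e1, e2))
    for (id in cci_ids()) {
      expect_equal(got$value[got$index == id], unname(expected[id]),
                   tolerance = 1e-12, label = paste("index", id))
    }
  }
})
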