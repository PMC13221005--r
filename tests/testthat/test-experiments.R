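test_that("surface grids match the constant-signal closed forms", {
  surf <- surface_study(resolution = 21)   # grid step 0.05 includes 0.5 and 1
  at <- function(id, a, b) {
    row <- surf[surf$index == id & abs(surf$e1 - a) < 1e-9 &
                  abs(surf$e2 - b) < 1e-9, ]
    row$value
  }
  expect_equal(at("SR", 0.5, 1), 0.5)
  expect_equal(at("FW", 0.5, 1), 2 / 3)
  expect_equal(at("UF", 0.5, 1), 0.5)
  expect_equal(at("R", 0.5, 1), 0.75)

  expect_equal(max(surf$value[surf$index == "UF"]), 1)
  expect_equal(max(surf$value[surf$index == "R"]), 2)
  expect_equal(at("UF", 1, 1), 1)
  expect_equal(at("R", 1, 1), 2)

  # symmetry under swapping the two amplitudes
  for (id in c("SR", "FW", "UF", "R")) {
    expect_equal(at(id, 0.3, 0.85), at(id, 0.85, 0.3))
  }

  # Thoroughman-Shadmehr undefined exactly on the diagonal, defined off it
  ts <- surf[surf$index == "TS", ]
  on_diag <- abs(ts$e1 - ts$e2) < 1e-9
  expect_true(all(!ts$defined[on_diag]))
  expect_true(all(ts$defined[!on_diag]))
})

test_that("the shape-based slice matches its closed forms and is increasing", {
  sl <- slice_study(e_high = 1, resolution = 51)
  expect_equal(sl$SR, sl$e_low, tolerance = 1e-12)
  expect_equal(sl$FW, 2 * sl$e_low / (1 + sl$e_low), tolerance = 1e-12)
  expect_equal(sl$TS, sl$e_low / (1 - sl$e_low), tolerance = 1e-12)
  expect_equal(unname(unlist(sl[1, c("SR", "FW", "TS")])), c(0, 0, 0))
  expect_true(all(diff(sl$SR) > 0))
  expect_true(all(diff(sl$FW) > 0))
  expect_true(all(diff(sl$TS) > 0))

  # same qualitative pattern at a different fixed higher envelope
  sl <- slice_study(e_high = 0.7, resolution = 30)
  expect_equal(sl$SR, sl$e_low / 0.7, tolerance = 1e-12)
  expect_true(all(diff(sl$TS) > 0))
})

test_that("normalization study: rescaling one signal moves the two index families differently", {
  ns <- normalization_study()
  expect_equal(nrow(ns), 36)
  val <- function(scen, idx) {
    sub <- ns[ns$scenario == scen & ns$index == idx, ]
    sub$value[order(-sub$peak)]   # peak 1.4, 1.0, 0.6
  }
  # lowering EMG2's peak reduces both overlap and total: amplitude-driven drop
  expect_true(all(diff(val("norm_A", "UF")) < 0))
  expect_true(all(diff(val("norm_A", "R")) < 0))
  # EMG2 stays the higher envelope: only the denominator shrinks, FW rises
  expect_true(all(diff(val("norm_B", "FW")) > 0))
  expect_true(all(diff(val("norm_B", "SR")) > 0))
  # the overlap is untouched in norm_B, so the mean lower envelope is constant
  expect_equal(diff(val("norm_B", "UF")), c(0, 0), tolerance = 1e-12)
})

test_that("joint rescaling of both signals is a normalization no-op for shape-based indices", {
  p <- gen_scenario("partial_overlap")
  base <- cci_all(p)
  for (k in c(0.6, 1.4)) {
    scaled <- cci_all(scale_pair(p, k))
    for (id in c("SR", "FW", "TS")) {
      expect_equal(scaled$value[scaled$index == id],
                   base$value[base$index == id], tolerance = 1e-12)
    }
  }
})

test_that("comparability study reproduces the three canonical overlap conditions", {
  cmp <- comparability_study()
  expect_equal(nrow(cmp), 18)

  none <- cmp[cmp$scenario == "no_overlap", ]
  expect_equal(none$value, rep(0, 6))

  full <- cmp[cmp$scenario == "complete_overlap", ]
  v <- function(tab, id) tab$value[tab$index == id]
  expect_equal(v(full, "SR"), 1)
  expect_equal(v(full, "FW"), 1)
  expect_equal(v(full, "UF"), 1)
  expect_equal(v(full, "R"), 2)
  expect_equal(v(full, "T"), 100)
  expect_false(full$defined[full$index == "TS"])

  part <- cmp[cmp$scenario == "partial_overlap", ]
  expect_true(all(part$defined))
  expect_true(all(part$value > 0))
  maxima <- c(SR = 1, FW = 1, TS = Inf, UF = 1, R = 2, T = 100)
  expect_true(all(part$value < maxima[part$index]))
  expect_equal(length(unique(part$value)), 6)   # indices disagree
})

test_that("sensitivity study: amplitude moves only amplitude-driven and temporal indices", {
  sens <- sensitivity_study()
  lo <- sens[sens$scenario == "sensitivity_low", ]
  hi <- sens[sens$scenario == "sensitivity_high", ]
  v <- function(tab, id) tab$value[tab$index == id]
  for (id in c("SR", "FW", "TS")) {
    expect_equal(v(lo, id), v(hi, id), tolerance = 1e-12)
  }
  expect_lt(v(lo, "UF"), v(hi, "UF"))
  expect_lt(v(lo, "R"), v(hi, "R"))
  expect_lt(v(lo, "T"), v(hi, "T"))   # longer supra-threshold overlap when high
})

test_that("a small correlation study is deterministic and well shaped", {
  a <- correlation_study(n_per_family = 30, seed = 5)
  b <- correlation_study(n_per_family = 30, seed = 5)
  expect_identical(a$cci, b$cci)
  expect_identical(a$xi, b$xi)

  expect_equal(nrow(a$cci), 3 * 30 * 6)
  expect_equal(sort(unique(a$cci$family)), c("poly1", "poly2", "sinusoid"))
  expect_equal(nrow(a$xi), 30)       # 6 x 5 ordered pairs
  expect_equal(nrow(a$xi_max), 15)   # 15 unordered pairs

  s <- correlation_summary(a$xi_max)
  expect_equal(s$stat, c("min_shape", "xi_amplitude", "min_nontemporal"))
  expect_true(all(is.finite(s$xi)))

  different <- correlation_study(n_per_family = 30, seed = 6)
  expect_false(identical(a$xi$xi, different$xi$xi))
})
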