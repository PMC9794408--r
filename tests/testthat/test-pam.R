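test_that("measured PAM signals carry the phycobilisome offset", {
  s <- fluorescence_signals(1, 4, 0.5, 2)
  expect_equal(apparent_signals(s), c(f0 = 2, fm = 5))
  expect_equal(apparent_signals(fluorescence_signals(1, 4, 0, 2)),
               c(f0 = 1, fm = 4))
  expect_equal(apparent_signals(fluorescence_signals(1, 4, 0.5, 0)),
               c(f0 = 1, fm = 4))
  expect_error(fluorescence_signals(4, 1, 0.5, 2))
  expect_error(fluorescence_signals(1, 4, 1.5, 2))
})

test_that("apparent Fv/Fm is depressed by contamination, exactly as derived", {
  clean <- fluorescence_signals(1, 4, 0, 2)
  expect_equal(apparent_fvfm(clean), 3 / 4)

  # bC = Fm with F0 = 0 halves the yield
  forced <- fluorescence_signals(0, 4, 0.5, 8)
  expect_equal(apparent_fvfm(forced), 0.5)

  # strictly decreasing in b and in C, bounded by the true ratio
  b_grid <- seq(0, 1, by = 0.1)
  vals_b <- vapply(b_grid, function(b)
    apparent_fvfm(fluorescence_signals(1, 4, b, 2)), numeric(1))
  expect_true(all(diff(vals_b) < 0))
  expect_true(all(vals_b <= 3 / 4))
  c_grid <- seq(0, 10, by = 1)
  vals_c <- vapply(c_grid, function(cc)
    apparent_fvfm(fluorescence_signals(1, 4, 0.3, cc)), numeric(1))
  expect_true(all(diff(vals_c) < 0))
})

test_that("a fractional change d in b moves apparent Fv/Fm by d/(2+d) at bC = Fm", {
  for (f0 in c(0, 0.5, 2)) {
    for (d in c(0.05, 0.10, 0.20)) {
      base <- fluorescence_signals(f0, 4, 0.5, 8)     # bC = Fm = 4
      up <- fluorescence_signals(f0, 4, 0.5 * (1 + d), 8)
      rel <- (apparent_fvfm(base) - apparent_fvfm(up)) / apparent_fvfm(base)
      expect_equal(rel, d / (2 + d), tolerance = 1e-12)
    }
  }
})

test_that("absorbed fraction follows A = 1 - 10^-D", {
  expect_equal(absorbed_fraction(c(0, 1, 2)), c(0, 0.9, 0.99))
  expect_error(absorbed_fraction(-0.1))
  d <- seq(0, 3, by = 0.1)
  expect_true(all(diff(absorbed_fraction(d)) > 0))
})

test_that("electron transport rate multiplies out and validates inputs", {
  expect_equal(etr(0.5, 100, absorbed = 0.9), 6.75)
  expect_equal(etr(0.5, 0, absorbed = 0.9), 0)
  expect_equal(etr(0.5, 100, absorbed = 0), 0)
  expect_error(etr(-0.1, 100, absorbed = 0.9))
  expect_error(etr(0.5, 100, absorbed = 1.2))
  expect_warning(etr(1.3, 100, absorbed = 0.9), "range")
})

test_that("noiseless tanh light curves are recovered to machine precision", {
  truth <- ground_truth(rlc = list(alpha = 0.3, etr_max = 10, noise_sd = 0,
                                   absorbed = 0.75))
  tab <- suppressWarnings(simulate_rlc(truth))  # alpha 0.3 implies yield > 1
  expect_true(is.finite(tab$yield[tab$e == 0]))
  expect_equal(suppressWarnings(etr(tab$yield[1], tab$e[1], 0.15, 0.75)), 0)

  fit <- suppressWarnings(fit_rlc(tab))
  expect_true(fit$converged)
  expect_equal(fit$alpha, 0.3, tolerance = 1e-7)
  expect_equal(fit$etr_max_fit, 10, tolerance = 1e-7)
  expect_equal(fit$ek, 10 / 0.3, tolerance = 1e-6)
  expect_lt(abs(fit$ek - fit$etr_max_fit / fit$alpha), 1e-9)
  expect_lt(fit$p_value, 1e-6)

  # fitted initial slope equals alpha in the light-limited limit
  e_small <- 1e-6
  slope <- fit$etr_max_fit * tanh(fit$alpha * e_small / fit$etr_max_fit) /
    e_small
  expect_equal(slope, fit$alpha, tolerance = 1e-6)
})

test_that("degenerate light curves are flagged, not raised", {
  dead <- rlc_table(c(0, 60, 120, 180, 240), rep(0, 5), absorbed = 0.75)
  fit <- fit_rlc(dead)
  expect_false(fit$converged)
  expect_true(is.na(fit$alpha))

  expect_error(fit_rlc(rlc_table(c(0, 60, 120), c(0.5, 0.4, 0.3),
                                 absorbed = 0.75)), "4 distinct")
})

test_that("median Ek is recovered within 10% across 200 noisy light curves", {
  truth <- ground_truth(rlc = list(alpha = 0.3, etr_max = 10,
                                   noise_sd = 0.02, absorbed = 0.75))
  eks <- vapply(1:200, function(i) {
    tab <- suppressWarnings(simulate_rlc(truth, seed = 5000 + i))
    fit <- suppressWarnings(fit_rlc(tab))
    if (fit$converged) fit$ek else NA_real_
  }, numeric(1))
  expect_gt(mean(!is.na(eks)), 0.95)
  expect_lt(abs(stats::median(eks, na.rm = TRUE) - 10 / 0.3) / (10 / 0.3),
            0.10)
})
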