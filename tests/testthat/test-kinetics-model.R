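test_that("populations satisfy the initial condition and decoupled limit", {
  m <- compartment_model()
  n0 <- solve_populations(m, c(0, 1))
  expect_equal(unname(n0[1, ]), c(1, 0, 0))

  # transfer switched off (huge transfer times): pure natural decay of A
  m_off <- compartment_model(tau_ab = 1e12, tau_bc = 1e12, tau_c = 220)
  t <- seq(0, 500, by = 10)
  n <- solve_populations(m_off, t)
  expect_equal(n[, "A"], exp(-t / 1000), tolerance = 1e-9)
  expect_lt(max(abs(n[, "B"])), 1e-9)
  expect_lt(max(abs(n[, "C"])), 1e-9)
})

test_that("closed-form Bateman cascade matches a fourth-order ODE oracle", {
  skip_if_not_installed("deSolve")
  cases <- list(compartment_model(),                    # exact kA == kB
                compartment_model(tau_ab = 37, tau_bc = 81, tau_c = 190),
                compartment_model(tau_ab = 60, tau_bc = 55,
                                  tau_c = 1 / (1 / 55 + 1 / 1000)))  # kB ~ kC
  t <- seq(0, 500, by = 1)
  for (m in cases) {
    kab <- 1 / m$tau_ab; kbc <- 1 / m$tau_bc
    ka <- kab + 1 / m$tau_da; kb <- kbc + 1 / m$tau_db; kc <- 1 / m$tau_c
    rhs <- function(t, y, p)
      list(c(-ka * y[1], kab * y[1] - kb * y[2], kbc * y[2] - kc * y[3]))
    ode <- deSolve::ode(c(1, 0, 0), t, rhs, NULL, method = "rk4",
                        hini = 0.05)
    n <- solve_populations(m, t)
    expect_lt(max(abs(n - ode[, 2:4])), 1e-8)
  }
})

test_that("populations conserve excitations once losses are integrated", {
  m <- compartment_model()
  t <- seq(0, 500, by = 0.25)
  n <- solve_populations(m, t)
  expect_true(all(n >= 0))
  loss_rate <- n[, "A"] / m$tau_da + n[, "B"] / m$tau_db + n[, "C"] / m$tau_c
  total <- rowSums(n) + as.vector(pracma::cumtrapz(t, loss_rate))
  expect_lt(max(abs(total - 1)), 1e-6)
})

test_that("near-degenerate rates join the analytic limit continuously", {
  t <- seq(0, 400, by = 2)
  exact <- solve_populations(compartment_model(tau_ab = 50, tau_bc = 50), t)
  nudged <- solve_populations(
    compartment_model(tau_ab = 50 * (1 + 2e-7), tau_bc = 50), t)
  expect_lt(max(abs(exact - nudged)), 1e-6)
})

test_that("Gaussian-convolved exponentials match direct quadrature", {
  k <- 1 / 80; fwhm <- 15; t0 <- 3
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  t <- seq(-30, 400, by = 7)
  for (ord in 0:2) {
    num <- vapply(t, function(ti) {
      lo <- max(0, ti - t0 - 10 * sigma)
      hi <- max(0, ti - t0 + 10 * sigma)
      if (hi <= lo) return(0)
      stats::integrate(function(x)
        x^ord * exp(-k * x) * stats::dnorm(ti - x, t0, sigma),
        lo, hi, rel.tol = 1e-12)$value
    }, numeric(1))
    an <- phycoflux:::emg_term(t, k, sigma, t0, ord)
    expect_lt(max(abs(num - an)) / max(abs(an)), 1e-6)
  }
})

test_that("IRF convolution preserves area and reduces to a shift", {
  t <- seq(-100, 900, by = 0.5)
  sig <- exp(-pmax(t, 0) / 60) * (t >= 0)
  expect_identical(convolve_irf(t, sig, irf_fwhm = 0, irf_t0 = 0), sig)

  conv <- convolve_irf(t, sig, irf_fwhm = 15, irf_t0 = 10)
  expect_equal(pracma::trapz(t, conv), pracma::trapz(t, sig),
               tolerance = 1e-6)
  # closed-form area of exp term through the analytic path: 1/k exactly
  an <- phycoflux:::emg_term(t, 1 / 60, phycoflux:::fwhm_to_sigma(15), 10, 0L)
  expect_equal(pracma::trapz(t, an), 60, tolerance = 1e-6)

  # smooth-pulse oracle: Gaussian (*) Gaussian is Gaussian with summed
  # variances, so the discrete path can be held to tight accuracy
  pulse <- dnorm(t, 100, 20)
  cpulse <- convolve_irf(t, pulse, irf_fwhm = 15, irf_t0 = 10)
  sig_irf <- phycoflux:::fwhm_to_sigma(15)
  expect_lt(max(abs(cpulse - dnorm(t, 110, sqrt(400 + sig_irf^2)))), 1e-6)

  expect_error(convolve_irf(c(0, 1, 3), c(1, 1, 1), 5), "uniform")
})

test_that("forward surface model is linear in the amplitudes", {
  m <- compartment_model()
  amps0 <- matrix(0, length(coarse_wl), 3)
  s0 <- predict_surface(m, amps0, coarse_time, coarse_wl)
  expect_true(all(s0$intensity == 0))

  # single compartment with a flat spectrum: rank-one surface
  amps1 <- cbind(rep(2, length(coarse_wl)), 0, 0)
  s1 <- predict_surface(m, amps1, coarse_time, coarse_wl)
  expect_equal(qr(s1$intensity)$rank, 1)

  expect_error(predict_surface(m, amps1[-1, ], coarse_time, coarse_wl),
               "amplitudes")
  expect_error(predict_surface(m, amps1, rev(coarse_time), coarse_wl),
               "increasing")
})

test_that("transfer efficiency follows the rate-competition formula", {
  expect_equal(transfer_efficiency(120, Inf), 1)
  expect_equal(transfer_efficiency(77, 77), 0.5)
  expect_equal(transfer_efficiency(120, 1500), (1/120) / (1/120 + 1/1500))
  expect_error(transfer_efficiency(-1, 10))
  expect_error(transfer_efficiency(10, 0))

  # strictly decreasing in transfer time, increasing in decay time
  taus <- seq(10, 400, by = 10)
  eff_t <- transfer_efficiency(taus, 1500)
  expect_true(all(diff(eff_t) < 0))
  eff_d <- transfer_efficiency(120, taus)
  expect_true(all(diff(eff_d) > 0))
})
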