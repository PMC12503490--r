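# Spectrum machinery, rigidity estimators and closed-form mechanics.

test_that("height field: flat fixture is zero, sinusoid is recovered", {
  g <- expand.grid(x = (0:29 + 0.5), y = (0:29 + 0.5))
  flat <- list(heads = cbind(g$x, g$y, 10), box = c(30, 30, 20))
  h <- height_field(flat, n_grid = 16)
  expect_true(all(abs(h) < 1e-12))
  expect_equal(mean(h), 0)

  A <- 0.8
  sin1 <- list(heads = cbind(g$x, g$y, 10 + A * cos(2 * pi * g$x / 30)),
               box = c(30, 30, 20))
  hs <- height_field(sin1, n_grid = 16)
  expect_equal(mean(hs), 0, tolerance = 1e-12)
  # amplitude of the fundamental mode along x
  amp <- 2 * Mod(fft(hs)[2, 1]) / 16^2
  expect_equal(amp, A, tolerance = 0.05)
})

test_that("height field flags frames with large holes", {
  g <- expand.grid(x = (0:29 + 0.5), y = (0:29 + 0.5))
  keep <- g$x > 18   # large empty region
  fr <- list(heads = cbind(g$x[keep], g$y[keep], 10), box = c(30, 30, 20))
  h <- height_field(fr, n_grid = 16)
  expect_true(attr(h, "flagged"))
})

# discrete q bins of an L-sided box up to qmax
.qbins <- function(L, qmax) {
  m <- expand.grid(mx = -8:8, my = -8:8)
  q <- 2 * pi * sqrt(m$mx^2 + m$my^2) / L
  sort(unique(round(q[q > 1e-9 & q < qmax], 6)))
}

test_that("forward-model spectra are recovered across the rigidity range", {
  L <- 40
  q <- .qbins(L, 1.0)
  set.seed(7)
  for (kappa in c(8, 20, 60)) for (lt in c(0.5, 2, 5)) {
    S <- spectrum_model(q, kappa, lt, L) * exp(rnorm(length(q), 0, 0.02))
    fit <- fit_spectrum(data.frame(q = q, S = S), L = L)
    expect_true(fit$converged)
    expect_equal(fit$kappa, kappa, tolerance = 0.10)
    if (lt >= 1)  # sub-sigma tilt lengths are below the fit's resolution
      expect_equal(fit$l_theta, lt, tolerance = 0.15)
  }
})

test_that("pure Helfrich limit: tilt fit degenerates gracefully", {
  L <- 40
  q <- .qbins(L, 0.52)
  S <- spectrum_model(q, 20, 0, L)
  fit <- fit_spectrum(data.frame(q = q, S = S), L = L)
  expect_equal(fit$kappa, 20, tolerance = 0.03)
  expect_lt(fit$l_theta, 0.5)
  expect_equal(fit$kappa_helfrich, 20, tolerance = 0.03)
})

test_that("Helfrich-only fit is biased when tilt matters", {
  # the tilt term adds q^-2 fluctuation power, so a pure 1/(kappa q^4)
  # model must raise its amplitude to compensate and reports a smaller
  # kappa; the bias grows with l_theta and is large beyond 2 sigma
  L <- 40
  q <- .qbins(L, 0.52)
  for (lt in c(3, 5)) {
    S <- spectrum_model(q, 20, lt, L)
    fit <- fit_spectrum(data.frame(q = q, S = S), L = L)
    expect_lt(fit$kappa_helfrich / fit$kappa, 0.80)
  }
  # ... but mild when l_theta is 1 sigma (tilt negligible below 2 sigma)
  S <- spectrum_model(q, 20, 1, L)
  fit <- fit_spectrum(data.frame(q = q, S = S), L = L)
  expect_gt(fit$kappa_helfrich / fit$kappa, 0.85)
})

test_that("fit range default keeps wavelengths above twice the thickness", {
  L <- 40
  q <- .qbins(L, 2)
  S <- spectrum_model(q, 20, 2, L)
  fit <- fit_spectrum(data.frame(q = q, S = S), L = L)
  expect_equal(fit$q_max, 2 * pi / 12)
  expect_true(all(fit$data$q < 2 * pi / 12))
  expect_error(fit_spectrum(data.frame(q = q[1:2], S = S[1:2]), L = L),
               "at least 4")
})

test_that("tilt persistence length formula and scaling", {
  expect_equal(tilt_persistence_length(12, 12), 1)      # kappa = kappa_theta
  expect_equal(tilt_persistence_length(20, 12), sqrt(20 / 12))
  expect_equal(tilt_persistence_length(40, 12),
               sqrt(2) * tilt_persistence_length(20, 12))
  expect_error(tilt_persistence_length(-1, 2), "positive")
})

test_that("two-state fit recovers generating constants exactly", {
  k <- seq(0, 3, by = 0.25)
  u <- 1 / (1 + exp(1 * (-0.16 + 3 * k)))
  fit <- two_state_fit(k, u, kT = 1)
  expect_equal(fit$c0, -0.16, tolerance = 1e-6)
  expect_equal(fit$c1, 3, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)
  expect_equal(predict(fit, 0), 1 / (1 + exp(-0.16)), tolerance = 1e-6)
  expect_equal(predict(fit, 0), 0.54, tolerance = 0.01)
})

test_that("c0 < 0 if and only if u_f(0) > 1/2", {
  k <- seq(0, 2, by = 0.2)
  for (c0 in c(-0.4, -0.16, 0.3)) {
    u <- 1 / (1 + exp(c0 + 2 * k))
    fit <- two_state_fit(k, u)
    expect_equal(fit$c0 < 0, predict(fit, 0) > 0.5)
  }
})

test_that("degenerate conformation data is flagged, not fitted", {
  expect_warning(fit <- two_state_fit(0:4, rep(0, 5)), "degenerate")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$c0))
})

test_that("fission barrier arithmetic", {
  expect_equal(fission_barrier(20, 40), 0)              # |kbar|/kappa = 2
  expect_equal(fission_barrier(20, 0.89 * 20), 4 * pi * 20 * 1.11)
  expect_equal(fission_barrier(20, 0.89 * 20), 278.97, tolerance = 1e-4)
  # increasing in kappa at fixed ratio
  expect_gt(fission_barrier(30, 0.89 * 30), fission_barrier(20, 0.89 * 20))
})

test_that("closure detector: closed shell yes, hemisphere no", {
  ffc <- forcefield_params(r_cargo = 4)
  closed <- build_wrapped_fixture(ffc, with_cargo = FALSE)
  open <- build_wrapped_fixture(ffc, coverage = 0.5, with_cargo = FALSE)
  expect_true(detect_closure(closed, ffc)$closed)
  expect_false(detect_closure(open, ffc)$closed)
})

test_that("Gaussian modulus estimator inverts synthetic closure data", {
  set.seed(11)
  kappa <- 10; lambda <- 2.4; r_star <- (2 * kappa + (-0.8 * kappa) * 1) ; NULL
  # choose a target kappa_bar and generate the implied critical radius
  kbar_true <- -8
  rstar_true <- 2 * (kbar_true + 2 * kappa) / lambda
  r <- rep(seq(rstar_true - 3, rstar_true + 3, length.out = 7), each = 12)
  closed <- runif(length(r)) < 1 / (1 + exp(-(r - rstar_true) / 0.4))
  est <- gaussian_modulus(data.frame(size = 1, r_disc = r, closed = closed),
                          kappa = kappa, lambda = lambda)
  expect_false(est$inconclusive)
  expect_equal(est$r_star, rstar_true, tolerance = 0.08)
  expect_equal(est$kappa_bar, kbar_true, tolerance = 0.15)
  expect_gt(est$ratio_se, 0)
  # all-closed ensembles are inconclusive
  allc <- gaussian_modulus(data.frame(size = 1, r_disc = r,
                                      closed = TRUE), kappa, lambda)
  expect_true(allc$inconclusive)
})

test_that("line tension arithmetic from run statistics", {
  stats <- data.frame(kex = 1.5, key = 2, kez = 2, wxx = -43,
                      wyy = 0, wzz = 0)
  expect_equal(line_tension(stats, box = c(10, 20, 20), axis = 1),
               -(2 * 1.5 - 43) / (2 * 10))
})
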