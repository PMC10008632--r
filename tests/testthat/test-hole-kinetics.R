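test_that("noiseless hole fit recovers the generator exactly", {
  hs <- simulateHoleSeries(aMax_um = 200, C_per_s = 2e-3, noiseSD_um = 0)
  fit <- fitHoleWidth(hs, nBoot = 0)
  expect_equal(fit@aMax_um, 200, tolerance = 1e-6)
  expect_equal(fit@C_per_s, 2e-3, tolerance = 1e-6)
  expect_lt(fit@residualSD_um, 1e-6)
})

test_that("the stretching time matches the 1 - 1/e crossing of the fit", {
  hs <- simulateHoleSeries(noiseSD_um = 5, seed = 11)
  fit <- fitHoleWidth(hs, nBoot = 0)
  # at t = 1/C the fitted curve reaches (1 - 1/e) a_max by construction;
  # solve the fitted curve numerically as an independent consistency check
  target <- (1 - exp(-1)) * fit@aMax_um
  tcross <- stats::uniroot(function(t)
    fit@aMax_um * (1 - exp(-fit@C_per_s * t)) - target,
    c(1, 1e6))$root
  expect_equal(tcross, 1 / fit@C_per_s, tolerance = 1e-6)
})

test_that("hole fit is invariant to a consistent time-origin shift", {
  hs <- simulateHoleSeries(noiseSD_um = 5, seed = 4)
  d <- seriesData(hs)
  shifted <- new("HoleSeries",
                 data = data.frame(t_s = d$t_s + 1800,
                                   width_um = d$width_um))
  f1 <- fitHoleWidth(hs, nBoot = 0)
  f2 <- fitHoleWidth(shifted, nBoot = 0)
  expect_equal(f1@aMax_um, f2@aMax_um, tolerance = 1e-8)
  expect_equal(f1@C_per_s, f2@C_per_s, tolerance = 1e-8)
})

test_that("hole fit rejects unusable series and reports bootstrap SEs", {
  dec <- new("HoleSeries",
             data = data.frame(t_s = seq(0, 1000, 100),
                               width_um = seq(200, 100, -10)))
  expect_error(fitHoleWidth(dec, nBoot = 0), "decreasing")
  short <- new("HoleSeries",
               data = data.frame(t_s = c(0, 100), width_um = c(0, 10)))
  expect_error(fitHoleWidth(short, nBoot = 0), "at least 5")
  fit <- fitHoleWidth(simulateHoleSeries(noiseSD_um = 5, seed = 2),
                      nBoot = 60, seed = 9)
  expect_true(all(is.finite(fit@se)))
  expect_gt(fit@se["C_per_s"], 0)
  # SEs should be commensurate with the true sampling spread (same order)
  expect_lt(fit@se["aMax_um"], 20)
})

test_that("tip parabola coefficient: closed form and grid-search oracle", {
  # exact points
  x <- seq(0, 1e-4, length.out = 30)
  prof <- data.frame(x_um = x * 1e6, y_um = 0.002 * sqrt(x) * 1e6)
  expect_equal(fitTipParabola(prof), 0.002, tolerance = 1e-12)
  # noisy points: compare against a brute-force scan of the objective
  set.seed(42)
  prof$y_um <- prof$y_um + rnorm(30, 0, 0.2)
  A_hat <- fitTipParabola(prof)
  grid <- seq(0.5 * A_hat, 1.5 * A_hat, length.out = 40001)
  sse <- vapply(grid, function(A)
    sum((prof$y_um * 1e-6 - A * sqrt(prof$x_um * 1e-6))^2), numeric(1))
  expect_equal(A_hat, grid[which.min(sse)], tolerance = 1e-4)
  expect_error(fitTipParabola(data.frame(x_um = c(0, 0), y_um = c(0, 1))),
               "undetermined")
})

test_that("material constants follow the scaling laws", {
  # k = E h / (C Rc^2): printed-order benchmark
  k <- deriveConstants(2e-3, E_Pa = 2000, h_m = 40e-6,
                       Rc_m = 200e-6)$k_Pa_s_m
  expect_equal(k, 1e9, tolerance = 1e-12)
  base <- deriveConstants(2e-3, E_Pa = 2000, h_m = 30e-6, Rc_m = 200e-6)
  expect_equal(deriveConstants(2e-3, E_Pa = 2000, h_m = 60e-6,
                               Rc_m = 200e-6)$k_Pa_s_m,
               2 * base$k_Pa_s_m)
  expect_equal(deriveConstants(2e-3, E_Pa = 2000, h_m = 30e-6,
                               Rc_m = 400e-6)$k_Pa_s_m,
               base$k_Pa_s_m / 4)
  # G = A^2 E inverts A = sqrt(G/E)
  G <- 1e-2; E <- 2000
  out <- deriveConstants(2e-3, E_Pa = E, A_m_sqrt = sqrt(G / E))
  expect_equal(out$G_J_m2, G, tolerance = 1e-12)
  expect_true(deriveConstants(2e-3)$hAssumed)
})
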