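test_that("generators are deterministic given the seed", {
  a <- simulateHoleSeries(noiseSD_um = 5, seed = 7)
  b <- simulateHoleSeries(noiseSD_um = 5, seed = 7)
  expect_identical(seriesData(a), seriesData(b))
  expect_false(identical(seriesData(a),
                         seriesData(simulateHoleSeries(noiseSD_um = 5,
                                                       seed = 8))))
  t1 <- simulateRoundingTrack(axisNoiseSD_um = 2, seed = 3)
  t2 <- simulateRoundingTrack(axisNoiseSD_um = 2, seed = 3)
  expect_identical(seriesData(t1), seriesData(t2))
  s1 <- simulateSpecklePair(displacement = c(1, 2), seed = 5)
  s2 <- simulateSpecklePair(displacement = c(1, 2), seed = 5)
  expect_identical(s1$frame1, s2$frame1)
})

test_that("hole width follows the exponential saturation law", {
  hs <- simulateHoleSeries(aMax_um = 200, C_per_s = 2e-3,
                           times_s = c(0, 500, 20 / 2e-3), noiseSD_um = 0)
  w <- seriesData(hs)$width_um
  expect_equal(w[1], 0)
  expect_equal(w[2], 200 * (1 - exp(-1)), tolerance = 1e-12)
  expect_lt(abs(w[3] - 200), 1e-8 * 200)
  expect_error(simulateHoleSeries(aMax_um = -1), "positive")
  expect_error(simulateHoleSeries(C_per_s = 0), "positive")
  expect_error(simulateHoleSeries(render = TRUE, imageShape = c(64, 64)),
               "too small")
})

test_that("hole tip profile samples y = A sqrt(x)", {
  A <- 0.002
  hs <- simulateHoleSeries(A_m_sqrt = A, noiseSD_um = 0)
  p <- hs@profile
  expect_gt(nrow(p), 0)
  expect_equal(p$y_um * 1e-6, A * sqrt(p$x_um * 1e-6), tolerance = 1e-12)
})

test_that("rounding track obeys the fixed-radius closed form", {
  # with |eps0| small the mean radius is nearly constant and
  # ln(eps/eps0) = -(15/56) (gamma/eta) t / r
  g <- 1e-8; r <- 100e-6; t <- 3600
  tr <- simulateRoundingTrack(eps0 = -0.01, gammaOverEta_m_s = g,
                              r0_um = 100, dt_s = 1200, nFrames = 4L,
                              integrationDt_s = 1)
  d <- seriesData(tr)
  ratio <- d$eps[4] / d$eps[1]
  expect_equal(log(ratio), -(15 / 56) * g * t / r, tolerance = 1e-3)
  expect_equal(exp(-0.09643), ratio, tolerance = 1e-3)
})

test_that("a sphere is a fixed point of the rounding dynamics", {
  tr <- simulateRoundingTrack(eps0 = 0, nFrames = 10L)
  d <- seriesData(tr)
  expect_true(all(d$eps == 0))
  expect_true(all(abs(d$circ - 1) < 1e-9))
  expect_error(simulateRoundingTrack(eps0 = -1), "degenerate")
})

test_that("rendered rounding masks reproduce the generated anisotropy", {
  tr <- simulateRoundingTrack(r0_um = 100, nFrames = 5L, dt_s = 14400,
                              render = TRUE, pixelSize = 1)
  mt <- labelAndTrack(attr(tr, "stack"), pixelSize = 1, dt_s = 14400)
  expect_length(mt, 1)
  expect_equal(seriesData(mt[[1]])$eps, seriesData(tr)$eps,
               tolerance = 0.02)
})

test_that("fusion series follows Frenkel sqrt-t growth with plateau", {
  fs <- simulateFusionSeries(R1_um = 100, R2_um = 100)
  expect_equal(fs@R0_um, 100)
  # reported-scale spot value: gamma/eta = 2.9e-9 m/s, R0 = 100 um, t = 1 h
  rho1h <- sqrt(2.9e-9 * 3600 * 100e-6) * 1e6
  expect_equal(rho1h, 32.3, tolerance = 0.01)
  d <- seriesData(simulateFusionSeries(dt_s = 3600, nFrames = 2L))
  expect_equal(d$rho_um[2], rho1h, tolerance = 1e-6)
  d <- seriesData(simulateFusionSeries(nFrames = 60L))
  expect_equal(d$rho_um[1], 0)
  expect_true(all(diff(d$rho_um) >= -1e-12))
  expect_true(all(d$rho_um <= 100 + 1e-9))
  # overlapping discs whose initial neck beats the plateau are rejected
  expect_error(simulateFusionSeries(centerDist_um = 120, plateau_um = 50),
               "exceeds the plateau")
  expect_error(simulateFusionSeries(R1_um = 100, R2_um = 20,
                                    centerDist_um = 50), "contains")
})

test_that("count series respects limits of the population law", {
  # p2 = 0: pure accumulation N = p1 t
  cs <- simulateCountSeries(p1 = 50, p2 = 0, ts_day = 8, noise = "none")
  d <- seriesData(cs)
  expect_equal(d$N, 50 * d$t_day, tolerance = 1e-10)
  # rise to one interior maximum then decay toward plateau p1/p2
  d <- seriesData(simulateCountSeries(p1 = 50, p2 = 1.5, ts_day = 8,
                                      horizon_day = 30, noise = "none"))
  imax <- which.max(d$N)
  expect_gt(imax, 1); expect_lt(imax, nrow(d))
  expect_true(all(diff(d$N[1:imax]) > 0))
  expect_true(all(diff(d$N[imax:nrow(d)]) < 1e-9))  # decay to the plateau
  expect_equal(d$N[nrow(d)], 50 / 1.5, tolerance = 1e-4)
  expect_error(simulateCountSeries(p1 = -5), "p1 > 0")
})

test_that("onset delay zero-pads the count series", {
  cs <- simulateCountSeries(onsetDelay_day = 3, noise = "none")
  d <- seriesData(cs)
  expect_true(all(d$N[d$t_day < 3] == 0))
  expect_gt(d$N[d$t_day == 4], 0)
})

test_that("von Mises angle generator matches its Bessel-ratio expectation", {
  # concentrated sample: Q near 1
  of <- simulateOrientationAngles(n = 1000L, kappa = 500, seed = 1)
  expect_gt(orderParameter(of), 0.99)
  expect_true(all(of@theta >= 0 & of@theta < pi))
  # kappa = 2: E[Q] = I1(2)/I0(2)
  of <- simulateOrientationAngles(n = 1e5, kappa = 2, seed = 2)
  expect_equal(orderParameter(of),
               besselI(2, 1) / besselI(2, 0), tolerance = 0.01)
  # kappa = 0: isotropic, Q small at n = 1e4
  q0 <- vapply(1:20, function(s)
    orderParameter(simulateOrientationAngles(n = 1e4, kappa = 0,
                                             seed = s)), numeric(1))
  expect_lt(stats::quantile(q0, 0.99), 0.03)
})

test_that("kappaForOrder inverts the Bessel ratio", {
  for (Q in c(0.18, 0.51, 0.87)) {
    k <- kappaForOrder(Q)
    expect_equal(besselI(k, 1) / besselI(k, 0), Q, tolerance = 1e-8)
  }
  expect_equal(kappaForOrder(0), 0)
})

test_that("speckle pair advects exactly by the displacement field", {
  sp <- simulateSpecklePair(displacement = c(0, 0), seed = 3)
  expect_identical(sp$frame1, sp$frame2)
  expect_false(sp$meta$displacementWarning)
  expect_warning(simulateSpecklePair(displacement = c(20, 0), seed = 3),
                 "exceeds")
})
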