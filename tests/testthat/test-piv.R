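test_that("identical frames give a zero field", {
  sp <- simulateSpecklePair(seed = 2)
  vf <- pivPair(sp$frame1, sp$frame1)
  d <- seriesData(vf)
  expect_true(all(d$valid))
  expect_lt(max(abs(c(d$u, d$v))), 1e-9)
})

test_that("a uniform subpixel shift is recovered within 0.1 px", {
  sp <- simulateSpecklePair(displacement = c(3.2, -1.7), seed = 2)
  d <- seriesData(pivPair(sp$frame1, sp$frame2))
  expect_lt(abs(stats::median(d$u[d$valid]) - 3.2), 0.1)
  expect_lt(abs(stats::median(d$v[d$valid]) + 1.7), 0.1)
})

test_that("the field is invariant to a common intensity rescaling", {
  sp <- simulateSpecklePair(displacement = c(2.4, 0.6), seed = 3)
  v1 <- seriesData(pivPair(sp$frame1, sp$frame2))
  v2 <- seriesData(pivPair(sp$frame1 * 2, sp$frame2 * 2))
  expect_equal(v1$u, v2$u, tolerance = 1e-12)
  expect_equal(v1$v, v2$v, tolerance = 1e-12)
})

test_that("recovered displacements are translation-equivariant", {
  # frame2 advected by (6.3, 2.1) instead of (3.3, -0.9): the recovered
  # field must differ by exactly the difference of the shifts
  spA <- simulateSpecklePair(displacement = c(3.3, -0.9), seed = 5)
  spB <- simulateSpecklePair(displacement = c(6.3, 2.1), seed = 5)
  dA <- seriesData(pivPair(spA$frame1, spA$frame2))
  dB <- seriesData(pivPair(spB$frame1, spB$frame2))
  ok <- dA$valid & dB$valid
  expect_lt(stats::median(abs((dB$u - dA$u)[ok] - 3)), 0.1)
  expect_lt(stats::median(abs((dB$v - dA$v)[ok] - 3)), 0.1)
})

test_that("a rigid rotation field has zero divergence and constant curl", {
  omega <- 0.2 * pi / 180
  ctr <- c(127.5, 127.5)
  rotField <- function(x, y)
    list(u = -omega * (y - ctr[2]), v = omega * (x - ctr[1]))
  sp <- simulateSpecklePair(displacement = rotField, seed = 6)
  d <- seriesData(pivPair(sp$frame1, sp$frame2))
  d <- d[d$valid, ]
  xs <- sort(unique(d$x_px)); ys <- sort(unique(d$y_px))
  h <- diff(xs)[1]
  U <- matrix(NA, length(xs), length(ys)); V <- U
  U[cbind(match(d$x_px, xs), match(d$y_px, ys))] <- d$u
  V[cbind(match(d$x_px, xs), match(d$y_px, ys))] <- d$v
  n <- length(xs)
  dUdx <- (U[3:n, 2:(n - 1)] - U[1:(n - 2), 2:(n - 1)]) / (2 * h)
  dVdy <- (V[2:(n - 1), 3:n] - V[2:(n - 1), 1:(n - 2)]) / (2 * h)
  dVdx <- (V[3:n, 2:(n - 1)] - V[1:(n - 2), 2:(n - 1)]) / (2 * h)
  dUdy <- (U[2:(n - 1), 3:n] - U[2:(n - 1), 1:(n - 2)]) / (2 * h)
  divg <- dUdx + dVdy; curl <- dVdx - dUdy
  expect_lt(stats::median(abs(divg), na.rm = TRUE), 0.2 * 2 * omega)
  expect_equal(stats::median(curl, na.rm = TRUE), 2 * omega,
               tolerance = 0.1)
})

test_that("3-SD filter removes injected outliers, keeps clean vectors", {
  # labeled-outlier simulation on a synthetic Gaussian field
  set.seed(11)
  g <- expand.grid(x_px = seq(16, 496, 16), y_px = seq(16, 496, 16))
  n <- nrow(g)
  g$u <- rnorm(n, 2, 0.3); g$v <- rnorm(n, -1, 0.3); g$valid <- TRUE
  out <- sample(n, round(0.05 * n))
  g$u[out] <- g$u[out] * 10; g$v[out] <- g$v[out] * 10
  vf <- new("VelocityField", data = g, dt_s = 300, pixelSize = 0.65,
            vrms_um_h = NA_real_, removedFraction = NA_real_)
  filt <- seriesData(filterVelocityField(vf))
  removedOut <- sum(!filt$valid[out]) / length(out)
  removedClean <- sum(!filt$valid[-out]) / (n - length(out))
  expect_gte(removedOut, 0.9)
  expect_lt(removedClean, 0.01)
})

test_that("clean Gaussian fields lose under 2% of vectors", {
  set.seed(13)
  g <- expand.grid(x_px = seq(16, 496, 16), y_px = seq(16, 496, 16))
  n <- nrow(g)
  g$u <- rnorm(n, 2, 0.5); g$v <- rnorm(n, 0, 0.5); g$valid <- TRUE
  vf <- new("VelocityField", data = g, dt_s = 300, pixelSize = 0.65,
            vrms_um_h = NA_real_, removedFraction = NA_real_)
  expect_lt(filterVelocityField(vf)@removedFraction, 0.02)
})

test_that("constant fields pass untouched with V_rms = |V0|", {
  g <- expand.grid(x_px = seq(16, 240, 16), y_px = seq(16, 240, 16))
  g$u <- 3; g$v <- 4; g$valid <- TRUE   # |V0| = 5 px/frame
  vf <- new("VelocityField", data = g, dt_s = 300, pixelSize = 0.65,
            vrms_um_h = NA_real_, removedFraction = NA_real_)
  filt <- filterVelocityField(vf)
  expect_equal(filt@removedFraction, 0)
  expect_equal(vrms(filt), 5 * 0.65 * 3600 / 300, tolerance = 1e-12)
})

test_that("unit conversion: 1 px/frame at 0.65 um/px, 5 min -> 7.8 um/h", {
  g <- expand.grid(x_px = seq(16, 240, 16), y_px = seq(16, 240, 16))
  g$u <- 1; g$v <- 0; g$valid <- TRUE
  vf <- new("VelocityField", data = g, dt_s = 300, pixelSize = 0.65,
            vrms_um_h = NA_real_, removedFraction = NA_real_)
  expect_equal(vrms(filterVelocityField(vf)), 7.8, tolerance = 1e-12)
})
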