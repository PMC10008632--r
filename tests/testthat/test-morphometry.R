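test_that("rendered discs give circular metrics", {
  m <- renderDiscMask(c(301, 301), 150, 150, 100)
  d <- seriesData(labelAndTrack(m, pixelSize = 1, dt_s = 1)[[1]])
  expect_gt(d$circ, 0.98); expect_lte(d$circ, 1.02)
  expect_lt(abs(d$eps), 0.02)
  expect_equal(d$area_um2, pi * 100^2, tolerance = 0.02)
  expect_equal(d$major_um, 100, tolerance = 0.02)
})

test_that("perimeter estimator converges on discs (<= 2% for R >= 30)", {
  for (R in c(30, 60, 120)) {
    m <- renderDiscMask(rep(2 * R + 41, 2), R + 20, R + 20, R)
    d <- seriesData(labelAndTrack(m, pixelSize = 1, dt_s = 1)[[1]])
    expect_lt(abs(d$perimeter_um - 2 * pi * R) / (2 * pi * R), 0.02)
  }
})

test_that("ellipse moments recover the semi-axes and anisotropy", {
  m <- renderEllipseMask(c(321, 321), 160, 160, 120, 60)
  d <- seriesData(labelAndTrack(m, pixelSize = 1, dt_s = 1)[[1]])
  expect_equal(d$major_um / d$minor_um, 2, tolerance = 0.03)
  expect_equal(d$eps, -1 / 3, tolerance = 0.02)
  expect_equal(d$r_um, (2 * 120 + 60) / 3, tolerance = 0.02)
})

test_that("large squares approach circularity pi/4", {
  m <- matrix(0, 340, 340); m[21:320, 21:320] <- 1
  d <- seriesData(labelAndTrack(m, pixelSize = 1, dt_s = 1)[[1]])
  expect_equal(d$circ, pi / 4, tolerance = 0.02)
})

test_that("metrics are invariant under whole-pixel translation", {
  m1 <- renderDiscMask(c(200, 200), 80, 80, 50)
  m2 <- renderDiscMask(c(200, 200), 97, 103, 50)
  d1 <- seriesData(labelAndTrack(m1, pixelSize = 1, dt_s = 1)[[1]])
  d2 <- seriesData(labelAndTrack(m2, pixelSize = 1, dt_s = 1)[[1]])
  expect_equal(d1$area_um2, d2$area_um2)
  expect_lt(abs(d1$circ - d2$circ), 1e-6)
})

test_that("labeling is 8-connected and respects min_area", {
  m <- matrix(0, 20, 20)
  m[3, 3] <- 1; m[4, 4] <- 1          # diagonal pair: one object
  lab <- labelMask8(m)
  expect_equal(max(lab), 1)
  m <- renderDiscMask(c(100, 100), 30, 50, 15) +
    renderDiscMask(c(100, 100), 70, 50, 3)
  trs <- labelAndTrack(pmin(m, 1), minArea_um2 = 100, pixelSize = 1,
                       dt_s = 1)
  expect_length(trs, 1)               # the 3 px disc is below min_area
})

test_that("tracking links objects across frames and is permutation-invariant", {
  mk <- function(x1, x2) pmin(
    renderDiscMask(c(220, 220), x1, 60, 25) +
      renderDiscMask(c(220, 220), x2, 160, 40), 1)
  stack <- list(mk(60, 150), mk(64, 154), mk(68, 158))
  trs <- labelAndTrack(stack, pixelSize = 1, dt_s = 10)
  expect_length(trs, 2)
  sizes <- vapply(trs, function(tr) seriesData(tr)$area_um2[1], numeric(1))
  small <- trs[[which.min(sizes)]]
  expect_equal(nrow(seriesData(small)), 3)
  expect_equal(diff(seriesData(small)$cx_um), c(4, 4), tolerance = 0.1)
  # permutation: mirror the mask so component label order flips
  stackM <- lapply(stack, function(m) m[, rev(seq_len(ncol(m)))])
  trsM <- labelAndTrack(stackM, pixelSize = 1, dt_s = 10)
  aM <- sort(vapply(trsM, function(tr) seriesData(tr)$area_um2[1],
                    numeric(1)))
  expect_equal(aM, sort(sizes))
  nM <- vapply(trsM, function(tr) nrow(seriesData(tr)), integer(1))
  expect_true(all(nM == 3))
})

test_that("hole width measurement round-trips the generator", {
  hs <- simulateHoleSeries(noiseSD_um = 0,
                           times_s = seq(0, 2000, length.out = 6),
                           render = TRUE, pixelSize = 1)
  mh <- measureHole(attr(hs, "stack"), pixelSize = 1, dt_s = 400)
  expect_equal(seriesData(mh)$width_um, seriesData(hs)$width_um,
               tolerance = 1 / 50)            # within ~1 px of 200 um scale
  expect_lt(max(abs(seriesData(mh)$width_um - seriesData(hs)$width_um)), 1)
})

test_that("hole measurement edge cases", {
  # full-frame background: no sheet, empty series
  empty <- measureHole(matrix(0, 60, 60), pixelSize = 1, dt_s = 1)
  expect_equal(nrow(seriesData(empty)), 0)
  # intact sheet: no enclosed hole, width 0
  intact <- measureHole(matrix(1, 60, 60), pixelSize = 1, dt_s = 1)
  expect_equal(nrow(seriesData(intact)), 0)   # never any hole
  # circular hole: width equals the diameter
  sheet <- 1 - renderDiscMask(c(200, 200), 100, 100, 40)
  mh <- measureHole(sheet, pixelSize = 1, dt_s = 1)
  expect_equal(seriesData(mh)$width_um, 80, tolerance = 1 / 80)
})

test_that("hole tip profile is parabolic for an elliptical hole", {
  # near its end an ellipse (a, b) looks like y = b sqrt(2 x / a):
  # the extracted contour profile must fit that coefficient
  sheet <- renderHoleMask(c(600, 400), 300, 200, 200, 80)
  mh <- measureHole(sheet, pixelSize = 1, dt_s = 1, profileFrame = 1,
                    caliper_px = 30)
  expect_gt(nrow(mh@profile), 10)
  A <- fitTipParabola(mh@profile)             # m^(1/2)
  A_expect <- 80 * sqrt(2 / 200) * sqrt(1e-6) # b*sqrt(2/a) in m^(1/2), px=um
  expect_equal(A, A_expect, tolerance = 0.1)
})

test_that("neck measurement round-trips the doublet generator", {
  fs <- simulateFusionSeries(nFrames = 8L, dt_s = 3600, render = TRUE,
                             pixelSize = 1)
  mn <- measureNeck(attr(fs, "stack"), centers = attr(fs, "centers_px"),
                    pixelSize = 1, dt_s = 3600)
  expect_lt(max(abs(seriesData(mn)$rho_um - seriesData(fs)$rho_um)), 1)
  expect_equal(mn@R0_um, fs@R0_um, tolerance = 0.01)
  expect_equal(mn@A1_um2, pi * 100^2, tolerance = 0.01)
})

test_that("fully merged circle necks at the object radius", {
  merged <- renderDiscMask(c(300, 300), 150, 150, 80)
  mn <- measureNeck(list(merged), centers = rbind(c(110, 150), c(190, 150)),
                    pixelSize = 1, dt_s = 1)
  # the minimal chord between the (interior) lobe centers is bounded by the
  # chord at the off-center scan, here >= 2*sqrt(80^2-40^2); the plateau
  # reading equals the disc's half-chord at the narrowest admissible scan
  expect_equal(seriesData(mn)$rho_um, sqrt(80^2 - 40^2), tolerance = 0.05)
  expect_error(
    measureNeck(list(pmin(renderDiscMask(c(200, 200), 40, 40, 15) +
                            renderDiscMask(c(200, 200), 100, 100, 15) +
                            renderDiscMask(c(200, 200), 160, 160, 15), 1)),
                centers = rbind(c(40, 40), c(160, 160)),
                pixelSize = 1, dt_s = 1),
    "lobes")
})

test_that("mask stacks survive a TIFF round trip bit-for-bit", {
  stack <- list(renderDiscMask(c(64, 64), 30, 30, 12),
                renderDiscMask(c(64, 64), 34, 30, 14))
  path <- tempfile(fileext = ".tif")
  writeMaskStack(stack, path)
  back <- readMaskStack(path)
  expect_length(back, 2)
  expect_equal(back[[1]], stack[[1]], ignore_attr = TRUE)
  expect_equal(back[[2]], stack[[2]], ignore_attr = TRUE)
})
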