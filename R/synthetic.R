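# Synthetic-data generators. Each generator emits the fitted kinetic law of
# the corresponding analysis stage plus configurable measurement noise; they
# are fixtures for the pipeline, not mechanistic cell simulations. All
# randomness flows through named substreams of one master seed, so equal
# configurations give bit-identical output and adding a modality never
# shifts another's draws.

#' Simulate a hole-opening width series
#'
#' Hole width follows the viscoelastic-fracture law
#' \eqn{a(t) = a_{max}[1 - \exp(-Ct)]} (elastic recoil resisted by
#' cell-substrate friction), with optional Gaussian measurement noise and an
#' optional near-tip edge profile sampled from the parabola
#' \eqn{y = A\sqrt{x}}.
#'
#' @param aMax_um saturation width (um); default 200, the reported experimental scale.
#' @param C_per_s rate constant (1/s); default 2e-3 (stretching time 500 s).
#' @param times_s sampling times (s). Default: 60 frames over 2000 s, about
#'   four stretching times.
#' @param noiseSD_um Gaussian SD of the width measurement (um); widths are
#'   clamped at zero.
#' @param A_m_sqrt optional parabola coefficient (units m^(1/2)); when given,
#'   \code{nProfile} tip points with x up to \code{profileExtent_um} are
#'   emitted.
#' @param profileNoiseSD_um Gaussian SD added to profile y (um).
#' @param nProfile,profileExtent_um tip-profile sampling controls.
#' @param seed master seed.
#' @param render if TRUE, also return a mask stack of an elongating
#'   elliptical hole in a foreground sheet.
#' @param pixelSize um per pixel for rendering.
#' @param imageShape rendered image size \code{c(nx, ny)} in px; must be
#'   large enough to contain the saturated hole.
#' @param holeAspect ratio of hole half-length to half-width when rendering.
#' @return a \code{HoleSeries}; when \code{render=TRUE} the mask stack is
#'   attached as attribute \code{"stack"}.
#' @export
simulateHoleSeries <- function(aMax_um = 200, C_per_s = 2e-3,
                               times_s = seq(0, 2000, length.out = 60),
                               noiseSD_um = 0, A_m_sqrt = NULL,
                               profileNoiseSD_um = 0, nProfile = 50L,
                               profileExtent_um = 100, seed = 1,
                               render = FALSE, pixelSize = 0.65,
                               imageShape = NULL, holeAspect = 2.5) {
  if (aMax_um <= 0 || C_per_s <= 0)
    stop("aMax_um and C_per_s must be strictly positive")
  stopifnot(noiseSD_um >= 0, all(times_s >= 0))
  width <- aMax_um * (1 - exp(-C_per_s * times_s))
  if (noiseSD_um > 0)
    width <- withSubstream(seed, "hole-width",
      pmax(0, width + stats::rnorm(length(width), 0, noiseSD_um)))
  profile <- data.frame(x_um = numeric(0), y_um = numeric(0))
  if (!is.null(A_m_sqrt)) {
    stopifnot(A_m_sqrt > 0)
    x_um <- seq(0, profileExtent_um, length.out = nProfile)
    y_um <- A_m_sqrt * sqrt(x_um * 1e-6) * 1e6
    if (profileNoiseSD_um > 0)
      y_um <- withSubstream(seed, "hole-profile",
        y_um + stats::rnorm(nProfile, 0, profileNoiseSD_um))
    profile <- data.frame(x_um = x_um, y_um = y_um)
  }
  out <- new("HoleSeries", data = data.frame(t_s = times_s, width_um = width),
             profile = profile,
             pixelSize = if (render) pixelSize else NA_real_)
  if (render) {
    if (is.null(imageShape))
      imageShape <- rep(ceiling(holeAspect * aMax_um / pixelSize) + 80L, 2)
    need <- holeAspect * aMax_um / pixelSize
    if (any(imageShape < need + 10))
      stop("imageShape too small to contain the saturated hole")
    ctr <- (imageShape - 1) / 2
    stack <- lapply(width, function(w) {
      hw <- w / 2 / pixelSize
      renderHoleMask(imageShape, ctr[1], ctr[2],
                     halfLength = hw * holeAspect, halfWidth = hw)
    })
    attr(out, "stack") <- stack
  }
  out
}

# integrate d(eps)/dt = -(15/56) (gamma/eta) eps / r(eps) at fixed volume,
# classical RK4; lengths in m, times in s
integrateAnisotropy <- function(eps0, gammaOverEta_m_s, V_m3, times_s,
                                dt_s = 60) {
  k0 <- (3 * V_m3 / (4 * pi))^(1 / 3)
  f <- function(eps) {
    if (eps == 0) return(0)
    q <- (1 + eps) / (1 - eps)
    a <- k0 * q^(-2 / 3)                  # inlined spheroidMeanRadius
    r <- (2 * a + a * q) / 3
    -(15 / 56) * gammaOverEta_m_s * eps / r
  }
  tmax <- max(times_s)
  nstep <- max(1L, ceiling(tmax / dt_s))
  h <- tmax / nstep
  tt <- numeric(nstep + 1); ee <- numeric(nstep + 1)
  tt[1] <- 0; ee[1] <- eps0
  for (i in seq_len(nstep)) {
    y <- ee[i]
    k1 <- f(y); k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    ee[i + 1] <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tt[i + 1] <- i * h
  }
  stats::approx(tt, ee, xout = times_s, rule = 2)$y
}

#' Simulate a cluster rounding-up track
#'
#' Integrates the active-dewetting anisotropy law
#' \eqn{d\epsilon/dt = -(15/56)(\gamma/\eta)\,\epsilon/r} on a
#' volume-conserving spheroid and emits the projected-ellipse morphometrics
#' frame by frame. Axis measurement noise is applied to the semi-axes, after
#' which major/minor are relabeled as a moments-based measurement would.
#'
#' @param eps0 initial anisotropy \eqn{(c-a)/(c+a)} in (-1, 0); default -0.4
#'   (an oblong cluster of circularity about 0.78).
#' @param gammaOverEta_m_s capillary velocity (m/s); default 1e-8, the
#'   reported rounding-up scale.
#' @param r0_um initial mean radius \eqn{(2a+c)/3} (um); default 100.
#' @param dt_s frame interval (s); default 1200 (one frame per 20 min).
#' @param nFrames number of frames; default 72 (24 h).
#' @param axisNoiseSD_um Gaussian SD added to each semi-axis (um).
#' @param seed master seed.
#' @param objectId track id.
#' @param integrationDt_s RK4 step (s).
#' @param render if TRUE, attach rasterized ellipse masks as attribute
#'   \code{"stack"}.
#' @param pixelSize um/px for rendering.
#' @param imageShape rendered image size (px).
#' @return a \code{ShapeTrack}; ground truth (noiseless eps, axes) is
#'   attached as attribute \code{"truth"}.
#' @export
simulateRoundingTrack <- function(eps0 = -0.4, gammaOverEta_m_s = 1e-8,
                                  r0_um = 100, dt_s = 1200, nFrames = 72L,
                                  axisNoiseSD_um = 0, seed = 1,
                                  objectId = 1L, integrationDt_s = 60,
                                  render = FALSE, pixelSize = 0.65,
                                  imageShape = NULL) {
  if (abs(eps0) >= 1) stop("|eps0| must be < 1 (degenerate spheroid)")
  stopifnot(gammaOverEta_m_s > 0, r0_um > 0, axisNoiseSD_um >= 0,
            nFrames >= 1)
  times <- (seq_len(nFrames) - 1L) * dt_s
  # initial axes from (eps0, r0): r = a(2 + q)/3 with q = c/a
  q0 <- (1 + eps0) / (1 - eps0)
  a0_m <- 3 * (r0_um * 1e-6) / (2 + q0)
  V_m3 <- spheroidVolume(a0_m, a0_m * q0)
  eps <- integrateAnisotropy(eps0, gammaOverEta_m_s, V_m3, times,
                             integrationDt_s)
  ax <- t(vapply(eps, function(e) spheroidAxes(e, V_m3), numeric(2)))
  a_um <- ax[, 1] * 1e6
  c_um <- ax[, 2] * 1e6
  truth <- data.frame(t_s = times, eps = eps, major_um = a_um,
                      minor_um = c_um)
  if (axisNoiseSD_um > 0) {
    noisy <- withSubstream(seed, "rounding-axes", {
      cbind(a_um + stats::rnorm(nFrames, 0, axisNoiseSD_um),
            c_um + stats::rnorm(nFrames, 0, axisNoiseSD_um))
    })
    noisy <- pmax(noisy, 1e-3)
    a_um <- pmax(noisy[, 1], noisy[, 2])
    c_um <- pmin(noisy[, 1], noisy[, 2])
  }
  area <- pi * a_um * c_um
  perim <- ellipsePerimeter(a_um, c_um)
  d <- data.frame(t_s = times, area_um2 = area, perimeter_um = perim,
                  circ = pmin(4 * pi * area / perim^2, 1),
                  major_um = a_um, minor_um = c_um,
                  eps = (c_um - a_um) / (c_um + a_um),
                  r_um = (2 * a_um + c_um) / 3,
                  cx_um = 0, cy_um = 0)
  out <- new("ShapeTrack", objectId = as.integer(objectId), data = d,
             pixelSize = if (render) pixelSize else NA_real_,
             flags = character(0))
  attr(out, "truth") <- truth
  if (render) {
    if (is.null(imageShape))
      imageShape <- rep(2L * ceiling(max(a_um) / pixelSize) + 40L, 2)
    ctr <- (imageShape - 1) / 2
    stack <- mapply(function(a, c.) {
      renderEllipseMask(imageShape, ctr[1], ctr[2], a / pixelSize,
                        c. / pixelSize)
    }, a_um, c_um, SIMPLIFY = FALSE)
    attr(out, "stack") <- stack
  }
  out
}

#' Simulate a cluster-fusion neck series
#'
#' Neck radius follows Frenkel viscous sintering,
#' \eqn{\rho(t) = \sqrt{(\gamma/\eta)\, t\, R_0}}, capped at a geometric
#' plateau (default the smaller cluster radius), with
#' \eqn{R_0 = \sqrt{(A_1+A_2)/(2\pi)}} from the initial areas.
#'
#' @param R1_um,R2_um initial cluster radii (um); observed fusing pairs have
#'   diameter about 200 um.
#' @param gammaOverEta_m_s capillary velocity (m/s); default 2.9e-9.
#' @param dt_s frame interval (s); default 1200.
#' @param nFrames number of frames; default 48 (16 h).
#' @param noiseSD_um Gaussian SD on the neck radius (um).
#' @param plateau_um plateau neck radius; default \code{min(R1_um, R2_um)}.
#' @param centerDist_um distance between disc centers for rendering; the
#'   default leaves a 3-pixel gap so pre-contact frames rasterize as
#'   detached lobes (tangent discs would show a spurious minimal chord).
#'   Initial overlap producing a neck wider than the plateau is rejected.
#' @param seed master seed.
#' @param render if TRUE, attach doublet masks (attribute \code{"stack"}).
#' @param pixelSize um/px for rendering.
#' @return a \code{FusionSeries} (attribute \code{"centers_px"} gives lobe
#'   centers when rendered).
#' @export
simulateFusionSeries <- function(R1_um = 100, R2_um = 100,
                                 gammaOverEta_m_s = 2.9e-9, dt_s = 1200,
                                 nFrames = 48L, noiseSD_um = 0,
                                 plateau_um = min(R1_um, R2_um),
                                 centerDist_um = R1_um + R2_um +
                                   3 * pixelSize, seed = 1,
                                 render = FALSE, pixelSize = 0.65) {
  stopifnot(R1_um > 0, R2_um > 0, gammaOverEta_m_s > 0, noiseSD_um >= 0,
            plateau_um > 0)
  if (centerDist_um < R1_um + R2_um) {
    # initial neck half-width of two overlapping circles
    d <- centerDist_um
    if (d <= abs(R1_um - R2_um))
      stop("one disc contains the other: invalid doublet geometry")
    x <- (d^2 - R2_um^2 + R1_um^2) / (2 * d)
    w0 <- sqrt(max(R1_um^2 - x^2, 0))
    if (w0 > plateau_um)
      stop("initial disc overlap exceeds the plateau geometry")
  }
  A1 <- pi * R1_um^2; A2 <- pi * R2_um^2
  R0_um <- sqrt((A1 + A2) / (2 * pi))
  times <- (seq_len(nFrames) - 1L) * dt_s
  rho <- pmin(sqrt(gammaOverEta_m_s * times * (R0_um * 1e-6)) * 1e6,
              plateau_um)
  if (noiseSD_um > 0)
    rho <- withSubstream(seed, "fusion-neck",
      pmax(0, rho + stats::rnorm(nFrames, 0, noiseSD_um)))
  out <- new("FusionSeries",
             data = data.frame(t_s = times, rho_um = rho),
             A1_um2 = A1, A2_um2 = A2, R0_um = R0_um)
  if (render) {
    Rpx <- c(R1_um, R2_um) / pixelSize
    dpx <- centerDist_um / pixelSize
    nx <- ceiling(dpx + 2 * sum(Rpx)) + 40L
    ny <- 2L * ceiling(max(Rpx)) + 40L
    c1 <- c((nx - 1) / 2 - dpx / 2, (ny - 1) / 2)
    c2 <- c((nx - 1) / 2 + dpx / 2, (ny - 1) / 2)
    stack <- lapply(rho / pixelSize, function(rp)
      renderDoubletMask(c(nx, ny), c1, c2, Rpx[1], Rpx[2], rp))
    attr(out, "stack") <- stack
    attr(out, "centers_px") <- rbind(c1, c2)
  }
  out
}

#' Simulate a cluster-count series
#'
#' Integrates the population dynamics
#' \eqn{dN/dt = p_1 - \alpha(t) p_2 N}, \eqn{\alpha(t)=\min(t/t_s,1)},
#' \eqn{N(0)=0}, samples it daily, and optionally adds Poisson or Gaussian
#' count noise and a pre-onset zero-padding delay emulating low seeding
#' densities.
#'
#' @param p1 cluster formation rate (clusters/day); reported fit 50.
#' @param p2 relative reduction rate (1/day); reported fit 1.5.
#' @param ts_day fusion-ramp stabilization time (day); reported fit 8.
#' @param horizon_day observation horizon (day); default 14.
#' @param noise one of "none", "poisson", "gaussian".
#' @param noiseSD Gaussian SD (counts) when \code{noise="gaussian"}.
#' @param onsetDelay_day zero-count days prepended before onset (default 0;
#'   3 emulates the low/medium seeding delay).
#' @param condition condition label.
#' @param seed master seed.
#' @param dt_day RK4 step (day).
#' @return a \code{CountSeries}.
#' @export
simulateCountSeries <- function(p1 = 50, p2 = 1.5, ts_day = 8,
                                horizon_day = 14, noise = "none",
                                noiseSD = 5, onsetDelay_day = 0,
                                condition = "synthetic", seed = 1,
                                dt_day = 1e-3) {
  stopifnot(p1 > 0, p2 >= 0, ts_day > 0, horizon_day > 0,
            onsetDelay_day >= 0)
  noise <- match.arg(noise, c("none", "poisson", "gaussian"))
  tt <- 0:floor(horizon_day)
  N <- simulatePopulation(p1, p2, ts_day, horizon_day, dt_day,
                          times_day = tt)$N
  if (noise == "poisson")
    N <- withSubstream(seed, "count-noise", stats::rpois(length(N), N))
  else if (noise == "gaussian")
    N <- withSubstream(seed, "count-noise",
                       pmax(0, N + stats::rnorm(length(N), 0, noiseSD)))
  t_out <- tt + onsetDelay_day
  if (onsetDelay_day > 0) {
    pre <- seq(0, onsetDelay_day - 1)
    t_out <- c(pre, t_out)
    N <- c(rep(0, length(pre)), N)
  }
  new("CountSeries",
      data = data.frame(t_day = t_out, N = N, condition = condition),
      onsetDay = NA_real_)
}

#' Simulate nematic fiber angles
#'
#' Draws \code{n} nematic angles \eqn{\theta \in [0,\pi)} with
#' \eqn{2\theta \sim \mathrm{vonMises}(2\mu, \kappa)}; \eqn{\kappa = 0}
#' gives an isotropic sample and large \eqn{\kappa} a nearly perfect
#' nematic. The expected order parameter is the Bessel ratio
#' \eqn{I_1(\kappa)/I_0(\kappa)}.
#'
#' @param n number of angles.
#' @param kappa von Mises concentration of the doubled angles.
#' @param mu mean fiber direction (radians).
#' @param seed master seed.
#' @return an \code{OrientationField}.
#' @export
simulateOrientationAngles <- function(n = 100L, kappa = 1, mu = 0,
                                      seed = 1) {
  stopifnot(n >= 1, kappa >= 0)
  th2 <- withSubstream(seed, "orientation", rvonmises(n, 2 * mu, kappa))
  new("OrientationField", theta = ((th2 / 2) %% pi), weight = numeric(0),
      reference = 0)
}

#' Simulate a speckle image pair with a known displacement field
#'
#' Frame 1 is a sum of Gaussian speckles at random subpixel positions;
#' frame 2 contains the same speckles advected by the supplied displacement
#' field (evaluated at each speckle center), which makes the warp exact to
#' machine precision. Ground truth for PIV round trips.
#'
#' @param shape image size \code{c(nx, ny)}.
#' @param displacement either \code{c(u, v)} in px for a uniform shift, or a
#'   \code{function(x, y)} returning \code{list(u=, v=)} evaluated at
#'   0-based pixel coordinates.
#' @param nSpeckles number of speckles; default fills ~2% of pixels.
#' @param speckleSigma Gaussian radius of one speckle (px).
#' @param contrast peak intensity of one speckle.
#' @param seed master seed.
#' @param maxDisplacement displacements beyond this (px) trigger a metadata
#'   warning (default 8 = 1/4 of the final 32 px PIV window).
#' @return list with \code{frame1}, \code{frame2} (matrices in [0,1]) and
#'   \code{meta} (speckle count, max displacement, warning flag).
#' @export
simulateSpecklePair <- function(shape = c(256, 256), displacement = c(0, 0),
                                nSpeckles = NULL, speckleSigma = 1.2,
                                contrast = 0.8, seed = 1,
                                maxDisplacement = 8) {
  if (is.null(nSpeckles))
    nSpeckles <- round(0.02 * prod(shape))
  dispFun <- if (is.function(displacement)) displacement else
    function(x, y) list(u = rep(displacement[1], length(x)),
                        v = rep(displacement[2], length(x)))
  pos <- withSubstream(seed, "speckle", {
    cbind(stats::runif(nSpeckles, 0, shape[1] - 1),
          stats::runif(nSpeckles, 0, shape[2] - 1))
  })
  d <- dispFun(pos[, 1], pos[, 2])
  maxd <- max(sqrt(d$u^2 + d$v^2))
  warned <- maxd > maxDisplacement
  if (warned)
    warning(sprintf(
      "max displacement %.1f px exceeds %.1f px: correlation may fail",
      maxd, maxDisplacement))
  splat <- function(px, py) {
    img <- matrix(0, shape[1], shape[2])
    w <- ceiling(4 * speckleSigma)
    for (i in seq_len(nrow(pos))) {
      x0 <- px[i]; y0 <- py[i]
      if (x0 < -w || x0 > shape[1] - 1 + w ||
          y0 < -w || y0 > shape[2] - 1 + w) next   # advected off-image
      xs <- max(0, floor(x0) - w):min(shape[1] - 1, ceiling(x0) + w)
      ys <- max(0, floor(y0) - w):min(shape[2] - 1, ceiling(y0) + w)
      patch <- contrast * exp(-(outer((xs - x0)^2, (ys - y0)^2, "+")) /
                                (2 * speckleSigma^2))
      img[xs + 1, ys + 1] <- img[xs + 1, ys + 1] + patch
    }
    pmin(img, 1)
  }
  list(frame1 = splat(pos[, 1], pos[, 2]),
       frame2 = splat(pos[, 1] + d$u, pos[, 2] + d$v),
       meta = list(nSpeckles = nSpeckles, maxDisplacement_px = maxd,
                   displacementWarning = warned, seed = seed))
}
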