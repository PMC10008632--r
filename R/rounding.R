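# Active dewetting of a cluster: surface tension drives the spheroid toward
# a sphere against bulk viscous dissipation, giving the anisotropy decay
# ln(eps/eps0) = -(15/56) (gamma/eta) * integral dt/r. Fitting the decay of
# measured anisotropy yields the capillary velocity gamma/eta.

#' Fit the rounding-up law and estimate the capillary velocity
#'
#' Per cluster, regresses \eqn{\ln(\epsilon/\epsilon_0)} on the cumulative
#' trapezoidal \eqn{\int dt/r} (the time-varying mean radius is used
#' exactly; set \code{assumeConstantR = TRUE} to use \eqn{t/\bar r} as a
#' constant-radius reading). The slope \eqn{s} gives
#' \eqn{\gamma/\eta = -(56/15)\,s}; per-cluster estimates are pooled by
#' inverse-variance weighting.
#'
#' Frames with \eqn{|\epsilon| <} \code{epsMin} are noise-dominated and
#' dropped; a track is truncated at its first anisotropy sign change (the
#' log law is undefined past it) and excluded entirely when fewer than 5
#' usable frames remain.
#'
#' @param tracks a \code{ShapeTrack} or list of them.
#' @param epsMin minimum usable |anisotropy| (default 0.01).
#' @param assumeConstantR use \eqn{t/\bar r} instead of the running
#'   integral.
#' @return a \code{RoundingFit}.
#' @export
fitRounding <- function(tracks, epsMin = 0.01, assumeConstantR = FALSE) {
  if (is(tracks, "ShapeTrack")) tracks <- list(tracks)
  rows <- list()
  for (tr in tracks) {
    d <- seriesData(tr)
    keep <- abs(d$eps) >= epsMin
    d <- d[keep, , drop = FALSE]
    if (nrow(d) >= 2) {
      flip <- which(sign(d$eps) != sign(d$eps[1]))
      if (length(flip)) d <- d[seq_len(flip[1] - 1L), , drop = FALSE]
    }
    if (nrow(d) < 5) {
      warning(sprintf(
        "track %d: fewer than 5 usable frames (|eps| >= %g): excluded",
        objectId(tr), epsMin))
      next
    }
    eps0 <- d$eps[1]
    y <- log(d$eps / eps0)
    r_m <- d$r_um * 1e-6
    t_s <- d$t_s - d$t_s[1]
    X <- if (assumeConstantR) t_s / mean(r_m) else
      pracma::cumtrapz(t_s, 1 / r_m)[, 1]
    fit <- stats::lm(y ~ X)
    sl <- stats::coef(fit)["X"]
    # suppressWarnings: summary.lm warns on noiseless (zero-residual) input
    sm <- suppressWarnings(summary(fit))
    rows[[length(rows) + 1L]] <- data.frame(
      track = objectId(tr), slope_m_s = unname(sl),
      se_m_s = sm$coefficients["X", "Std. Error"],
      gammaOverEta_m_s = -(56 / 15) * unname(sl), eps0 = eps0,
      r2 = sm$r.squared, nUsed = nrow(d))
  }
  if (!length(rows))
    stop("all tracks excluded: no usable anisotropy decay to fit")
  per <- do.call(rbind, rows)
  w <- 1 / per$se_m_s^2
  # an exact (zero-SE) track would get infinite weight: split it evenly
  if (any(!is.finite(w))) w <- ifelse(is.finite(w), 0, 1)
  pooledSlope <- sum(per$slope_m_s * w) / sum(w)
  pooledSE <- sqrt(1 / sum(w)) * (56 / 15)
  g <- -(56 / 15) * pooledSlope
  if (g <= 0)
    stop("pooled anisotropy slope is non-negative: clusters are not rounding")
  new("RoundingFit", gammaOverEta_m_s = g, se_m_s = pooledSE, perTrack = per)
}

# ---- dissipation-rate diagnostic -------------------------------------------

# Affine incompressible flow ansatz for a spheroid relaxing at rate
# eps_dot: u = (ec*x, ec*y, ea*z) with the distinct axis `a` along z and
# ea + 2*ec = 0. Returns the (constant) velocity-gradient diagonal per unit
# eps_dot together with the axis strain rates.
affineAnsatz <- function(eps, V) {
  ax <- spheroidAxes(eps, V)
  a <- ax["a"]; c <- ax["c"]
  # da/deps, dc/deps at constant volume (analytic)
  q <- (1 + eps) / (1 - eps)
  dq <- 2 / (1 - eps)^2
  dlna <- -(2 / 3) * dq / q    # a ~ q^(-2/3)
  dlnc <- (1 / 3) * dq / q     # c ~ q^(1/3)
  list(ea = unname(dlna), ec = unname(dlnc), a = unname(a), c = unname(c))
}

# integral of grad(u):grad(u) over the spheroid for a pluggable gradient
# field gradFun(x, y, z) -> 3x3 matrix; Gauss-Legendre product quadrature on
# the unit ball mapped to the spheroid (distinct axis a along z).
dissipationIntegral <- function(gradFun, a, c, nq = 24) {
  gl <- pracma::gaussLegendre(nq, 0, 1)       # radial
  glc <- pracma::gaussLegendre(nq, -1, 1)     # cos(polar)
  glp <- pracma::gaussLegendre(nq, 0, 2 * pi) # azimuth
  total <- 0
  for (i in seq_len(nq)) for (j in seq_len(nq)) {
    r <- gl$x[i]; ct <- glc$x[j]; st <- sqrt(1 - ct^2)
    for (k in seq_len(nq)) {
      ph <- glp$x[k]
      x <- c * r * st * cos(ph); y <- c * r * st * sin(ph); z <- a * r * ct
      g <- gradFun(x, y, z)
      total <- total + gl$w[i] * glc$w[j] * glp$w[k] *
        r^2 * sum(g * g)
    }
  }
  total * a * c^2   # Jacobian of the unit-ball mapping
}

#' Dissipation-rate diagnostic for the rounding prefactor
#'
#' Evaluates both sides of the energy balance
#' \eqn{\gamma \dot S = -\eta \int_V \nabla u : \nabla u\, dV} on a
#' volume-conserving spheroid near a sphere, for a pluggable interior
#' velocity-field ansatz, and reports the implied relaxation-rate prefactor
#' \eqn{\lambda} in \eqn{\dot\epsilon = -\lambda (\gamma/\eta) \epsilon / r}
#' for comparison against the model's 15/56. Diagnostic only: the default
#' affine incompressible ansatz is not the variational optimum, so the
#' implied prefactor need not equal 15/56 and is reported, never asserted.
#'
#' @param eps anisotropy at which to evaluate (|eps| <= 0.05 for the
#'   near-sphere regime).
#' @param r_um mean radius (um), fixing the spheroid volume.
#' @param ansatz \code{"affine"} or a \code{function(eps, V)} returning
#'   \code{list(gradFun = function(x,y,z) 3x3 matrix per unit eps_dot)}.
#' @param nq quadrature nodes per dimension.
#' @return list with \code{dS_deps} (exact-area finite difference),
#'   \code{dissipationPerRate2} (\eqn{\int |\nabla u|^2 dV} per unit
#'   \eqn{\dot\epsilon^2}), \code{impliedPrefactor}, and the geometry.
#' @export
dissipationCheck <- function(eps, r_um = 100, ansatz = "affine", nq = 24) {
  if (abs(eps) > 0.05)
    stop("diagnostic is valid only near the sphere (|eps| <= 0.05)")
  # work in metres; choose V so the mean radius at this eps equals r_um
  r_m <- r_um * 1e-6
  V <- (r_m / as.numeric(spheroidMeanRadius(eps, 1)))^3
  if (eps == 0) {
    return(list(dS_deps = 0, dissipationPerRate2 = 0, impliedPrefactor = NA,
                note = "sphere: zero area change and zero required dissipation",
                V_m3 = V, r_m = r_m))
  }
  if (is.character(ansatz) && ansatz == "affine") {
    an <- affineAnsatz(eps, V)
    div <- an$ea + 2 * an$ec
    if (abs(div) > 1e-8 * max(abs(an$ea), abs(an$ec)))
      stop("ansatz is not volume-conserving (nonzero divergence)")
    gradFun <- function(x, y, z) diag(c(an$ec, an$ec, an$ea))
    a <- an$a; c <- an$c
  } else {
    stopifnot(is.function(ansatz))
    an <- ansatz(eps, V)
    gradFun <- an$gradFun
    ax <- spheroidAxes(eps, V); a <- ax["a"]; c <- ax["c"]
    tr <- sum(diag(gradFun(0, 0, 0)))
    if (abs(tr) > 1e-8)
      stop("ansatz is not volume-conserving (nonzero divergence)")
  }
  dS <- unname(spheroidAreaDeriv(eps, V))
  D <- unname(dissipationIntegral(gradFun, a, c, nq))  # per unit eps_dot^2
  # gamma * dS/deps * eps_dot = -eta * D * eps_dot^2
  # with eps_dot = -lambda (gamma/eta) eps / r  =>  lambda = dS * r / (D eps)
  lambda <- dS * r_m / (D * eps)
  list(dS_deps = dS, dissipationPerRate2 = D, impliedPrefactor = lambda,
       a_m = unname(a), c_m = unname(c), V_m3 = V, r_m = r_m)
}
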