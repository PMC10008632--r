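# Hole-opening kinetics: the width of a contractility-induced hole in the
# cell sheet follows a(t) = a_max [1 - exp(-C t)] (elastic recoil resisted
# by cell-substrate friction), and the near-tip edge profile is the parabola
# y = A sqrt(x) of a viscoelastic crack.

#' Fit the hole-opening width law
#'
#' Nonlinear least squares of \eqn{a(t) = a_{max}[1-\exp(-Ct)]} with
#' multi-start initialization (\eqn{a_{max}^0} = max width, \eqn{C^0} on a
#' decade grid) and pairs-bootstrap standard errors (bootstrap over time
#' points, robust to heteroscedastic noise). The time origin is shifted to
#' the first frame with nonzero width, since the law presumes \eqn{a(0)=0}.
#'
#' @param series a \code{HoleSeries}.
#' @param nBoot bootstrap resamples (default 1000; 0 skips SEs).
#' @param seed seed for the bootstrap.
#' @return a \code{HoleFit}.
#' @export
fitHoleWidth <- function(series, nBoot = 1000L, seed = 1) {
  d <- seriesData(series)
  if (nrow(d) < 5) stop("need at least 5 time points")
  # time origin = first frame with nonzero width (hole nucleation)
  i0 <- which(d$width_um > 0)
  if (!length(i0)) stop("no nonzero widths: nothing to fit")
  t0 <- if (i0[1] > 1) d$t_s[i0[1] - 1] else d$t_s[1]
  d$t_s <- d$t_s - t0
  d <- d[d$t_s >= 0, , drop = FALSE]
  if (stats::cor(d$t_s, d$width_um) < 0)
    stop("monotone-decreasing series: not an opening hole")
  span <- diff(range(d$t_s))
  fitOnce <- function(dat) {
    best <- NULL
    for (C0 in 10^seq(-5, -1)) {
      f <- tryCatch(
        minpack.lm::nlsLM(width_um ~ aMax * (1 - exp(-C * t_s)),
                          data = dat,
                          start = list(aMax = max(dat$width_um), C = C0),
                          lower = c(1e-12, 1e-12),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f) &&
          (is.null(best) || stats::deviance(f) < stats::deviance(best)))
        best <- f
    }
    best
  }
  fit <- fitOnce(d)
  if (is.null(fit))
    stop("hole-width fit did not converge from any start (decade grid ",
         "C0 in 1e-5..1e-1)")
  cf <- stats::coef(fit)
  if (1 / cf["C"] > 5 * span)
    warning("data span less than one stretching time: C poorly constrained")
  se <- c(aMax_um = NA_real_, C_per_s = NA_real_)
  if (nBoot > 0) {
    bs <- withSubstream(seed, "hole-boot", {
      vapply(seq_len(nBoot), function(b) {
        idx <- sample.int(nrow(d), replace = TRUE)
        fb <- tryCatch(fitOnce(d[idx, , drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(fb)) rep(NA_real_, 2) else stats::coef(fb)
      }, numeric(2))
    })
    se <- apply(bs, 1, stats::sd, na.rm = TRUE)
    names(se) <- c("aMax_um", "C_per_s")
  }
  pred <- stats::predict(fit)
  new("HoleFit", aMax_um = unname(cf["aMax"]), C_per_s = unname(cf["C"]),
      se = se, residualSD_um = stats::sd(d$width_um - pred),
      fitted = data.frame(t_s = d$t_s, width_um = d$width_um,
                          fit_um = pred, resid_um = d$width_um - pred),
      nBoot = as.integer(nBoot))
}

#' Fit the crack-tip parabola
#'
#' Least-squares coefficient of \eqn{y = A\sqrt{x}} for edge-profile points
#' in the propagation frame; closed form
#' \eqn{A = \sum y\sqrt{x} / \sum x}.
#'
#' @param profile data.frame with columns \code{x_um}, \code{y_um} (or a
#'   \code{HoleSeries}, whose profile slot is used), x >= 0.
#' @return the coefficient A in m^(1/2) (fracture scaling: \eqn{A \sim
#'   \sqrt{G/E}} links it to adhesion energy and sheet modulus).
#' @export
fitTipParabola <- function(profile) {
  if (is(profile, "HoleSeries")) profile <- profile@profile
  stopifnot(all(c("x_um", "y_um") %in% names(profile)))
  x <- profile$x_um * 1e-6
  y <- profile$y_um * 1e-6
  if (any(x < 0)) stop("profile x must be non-negative")
  if (all(x == 0)) stop("all profile points at the tip: A is undetermined")
  sum(y * sqrt(x)) / sum(x)
}

#' Derive material constants from a hole fit
#'
#' Cell-substrate friction \eqn{k = E h / (C R_c^2)} from the fitted rate
#' constant, and adhesion energy \eqn{G = A^2 E} when the tip-parabola
#' coefficient is supplied. Inputs are echoed for provenance.
#'
#' @param fit a \code{HoleFit} (or a numeric rate constant C in 1/s).
#' @param E_Pa sheet elastic modulus (Pa); reported estimates are ~2 kPa.
#' @param h_m sheet thickness (m). Never printed in the source study;
#'   default 30e-6 (three 10-um layers, the typical pre-cluster stack),
#'   flagged in the output.
#' @param Rc_m cell size (m); ~200e-6.
#' @param A_m_sqrt optional tip-parabola coefficient (m^(1/2)).
#' @return named list with \code{k_Pa_s_m}, \code{G_J_m2} (NA when A absent),
#'   \code{stretchingTime_s}, the inputs, and \code{hAssumed} = TRUE when the
#'   default thickness was used.
#' @export
deriveConstants <- function(fit, E_Pa = 2000, h_m = 30e-6, Rc_m = 200e-6,
                            A_m_sqrt = NULL) {
  C <- if (is(fit, "HoleFit")) fit@C_per_s else as.numeric(fit)
  stopifnot(C > 0, E_Pa > 0, h_m > 0, Rc_m > 0)
  hAssumed <- missing(h_m)
  k <- E_Pa * h_m / (C * Rc_m^2)
  G <- if (!is.null(A_m_sqrt)) A_m_sqrt^2 * E_Pa else NA_real_
  list(k_Pa_s_m = k, G_J_m2 = G, stretchingTime_s = 1 / C,
       inputs = list(C_per_s = C, E_Pa = E_Pa, h_m = h_m, Rc_m = Rc_m,
                     A_m_sqrt = A_m_sqrt),
       hAssumed = hAssumed)
}
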