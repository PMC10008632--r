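# Frenkel viscous sintering: two coalescing viscous drops grow a contact
# neck with rho^2 / R0 = (gamma/eta) * t until geometric saturation.

#' Fit Frenkel sintering to a neck-growth series
#'
#' Detects first contact (first frame with \eqn{\rho} above one pixel),
#' estimates the plateau as the median of the last quartile of \eqn{\rho},
#' restricts to the growth phase (\eqn{\rho < 0.9\,\rho_\infty}, cutoff
#' exposed), and fits the through-origin regression of \eqn{\rho^2/R_0}
#' against time since contact. The slope is the capillary velocity
#' \eqn{\gamma/\eta} in m/s.
#'
#' @param series a \code{FusionSeries} (with R0 recorded).
#' @param growthCutoff growth-phase cutoff as a fraction of the plateau
#'   (default 0.9; Frenkel's law holds before geometric saturation).
#' @param pixelSize_um pixel size used for the one-pixel contact threshold.
#' @return a \code{FusionFit}.
#' @export
fitFrenkel <- function(series, growthCutoff = 0.9, pixelSize_um = 0.65) {
  d <- seriesData(series)
  R0_um <- series@R0_um
  if (is.na(R0_um)) stop("FusionSeries has no R0: record initial areas first")
  contact <- which(d$rho_um > pixelSize_um)
  if (!length(contact)) stop("lobes never in contact: nothing to fit")
  i0 <- contact[1]
  # time origin: the frame before first contact (rho(0) = 0)
  t0 <- if (i0 > 1) d$t_s[i0 - 1] else d$t_s[1]
  d <- d[d$t_s >= t0, , drop = FALSE]
  d$t_s <- d$t_s - t0
  plateau <- stats::median(d$rho_um[d$t_s >= stats::quantile(d$t_s, 0.75)])
  grow <- which(d$rho_um < growthCutoff * plateau & d$t_s > 0)
  if (length(grow) < 4)
    stop(sprintf("only %d growth-phase points (need >= 4)", length(grow)))
  y <- (d$rho_um[grow] * 1e-6)^2 / (R0_um * 1e-6)   # metres
  t <- d$t_s[grow]
  fit <- stats::lm(y ~ 0 + t)
  slope <- unname(stats::coef(fit)["t"])
  if (slope <= 0) stop("negative sintering slope: not a fusing pair")
  # suppressWarnings: summary.lm warns on noiseless (zero-residual) input
  se <- suppressWarnings(summary(fit))$coefficients["t", "Std. Error"]
  ybar <- mean(y)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - ybar)^2)
  new("FusionFit", gammaOverEta_m_s = slope, se_m_s = se, R0_um = R0_um,
      plateau_um = plateau, growthIdx = as.integer(grow), r2 = r2)
}

#' Pool Frenkel fits across cluster pairs
#'
#' Fits each pair separately and reports mean and SD of the capillary
#' velocity across pairs (mirroring a mean-over-N-pairs summary).
#'
#' @param seriesList list of \code{FusionSeries}.
#' @param ... passed to \code{\link{fitFrenkel}}.
#' @return list with \code{mean_m_s}, \code{sd_m_s}, \code{n}, and the
#'   individual \code{fits}.
#' @export
poolFrenkel <- function(seriesList, ...) {
  fits <- lapply(seriesList, fitFrenkel, ...)
  g <- vapply(fits, gammaOverEta, numeric(1))
  list(mean_m_s = mean(g), sd_m_s = stats::sd(g), n = length(g),
       fits = fits)
}
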