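#' @import methods
NULL

.checkCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    return(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")))
  NULL
}

#' ShapeTrack: per-object morphometric time series
#'
#' Container for the per-frame shape metrics of one tracked object: area,
#' perimeter, circularity \eqn{4\pi A/P^2}, ellipse semi-axes, anisotropy
#' \eqn{\epsilon = (c-a)/(c+a)} (major semi-axis \eqn{a}, minor \eqn{c}, so
#' \eqn{\epsilon \le 0}), mean radius \eqn{r=(2a+c)/3} and centroid.
#'
#' @slot objectId integer object/track identifier.
#' @slot data data.frame with columns \code{t_s}, \code{area_um2},
#'   \code{perimeter_um}, \code{circ}, \code{major_um}, \code{minor_um},
#'   \code{eps}, \code{r_um}, \code{cx_um}, \code{cy_um}.
#' @slot pixelSize length per pixel in micrometres (NA when not image-derived).
#' @slot flags character vector of quality warnings (e.g. clamped circularity).
#' @export
setClass("ShapeTrack",
  representation(objectId = "integer", data = "data.frame",
                 pixelSize = "numeric", flags = "character"),
  prototype(objectId = 1L,
            data = data.frame(t_s = numeric(0), area_um2 = numeric(0),
                              perimeter_um = numeric(0), circ = numeric(0),
                              major_um = numeric(0), minor_um = numeric(0),
                              eps = numeric(0), r_um = numeric(0),
                              cx_um = numeric(0), cy_um = numeric(0)),
            pixelSize = NA_real_, flags = character(0)))

setValidity("ShapeTrack", function(object) {
  d <- object@data
  msg <- .checkCols(d, c("t_s", "area_um2", "perimeter_um", "circ",
                         "major_um", "minor_um", "eps", "r_um",
                         "cx_um", "cy_um"), "ShapeTrack@data")
  if (!is.null(msg)) return(msg)
  if (nrow(d)) {
    if (any(d$area_um2 <= 0, na.rm = TRUE)) return("area must be positive")
    if (any(d$perimeter_um <= 0, na.rm = TRUE))
      return("perimeter must be positive")
    if (any(d$circ > 1.02 + 1e-9, na.rm = TRUE))
      return("circularity exceeds 1.02: measurement failure")
    if (any(d$r_um <= 0, na.rm = TRUE)) return("mean radius must be positive")
    if (any(d$eps <= -1 | d$eps >= 1, na.rm = TRUE))
      return("anisotropy must lie in (-1, 1)")
  }
  TRUE
})

#' HoleSeries: hole width over time, with optional tip profile
#'
#' @slot data data.frame with columns \code{t_s}, \code{width_um}.
#' @slot profile data.frame with columns \code{x_um}, \code{y_um}: edge
#'   points near the crack tip, in the propagation frame (x along the
#'   propagation direction, x >= 0 at the tip).
#' @slot pixelSize length per pixel (um), NA when not image-derived.
#' @export
setClass("HoleSeries",
  representation(data = "data.frame", profile = "data.frame",
                 pixelSize = "numeric"),
  prototype(data = data.frame(t_s = numeric(0), width_um = numeric(0)),
            profile = data.frame(x_um = numeric(0), y_um = numeric(0)),
            pixelSize = NA_real_))

setValidity("HoleSeries", function(object) {
  msg <- .checkCols(object@data, c("t_s", "width_um"), "HoleSeries@data")
  if (!is.null(msg)) return(msg)
  msg <- .checkCols(object@profile, c("x_um", "y_um"), "HoleSeries@profile")
  if (!is.null(msg)) return(msg)
  if (any(object@data$width_um < 0, na.rm = TRUE))
    return("hole widths must be non-negative")
  if (any(object@profile$x_um < 0, na.rm = TRUE))
    return("profile x must be non-negative (distance behind the tip)")
  TRUE
})

#' FusionSeries: neck radius over time for a coalescing cluster pair
#'
#' @slot data data.frame with columns \code{t_s}, \code{rho_um}.
#' @slot A1_um2,A2_um2 initial projected areas of the two clusters (um^2).
#' @slot R0_um effective initial radius \eqn{R_0=\sqrt{(A_1+A_2)/(2\pi)}}.
#' @export
setClass("FusionSeries",
  representation(data = "data.frame", A1_um2 = "numeric", A2_um2 = "numeric",
                 R0_um = "numeric"),
  prototype(data = data.frame(t_s = numeric(0), rho_um = numeric(0)),
            A1_um2 = NA_real_, A2_um2 = NA_real_, R0_um = NA_real_))

setValidity("FusionSeries", function(object) {
  msg <- .checkCols(object@data, c("t_s", "rho_um"), "FusionSeries@data")
  if (!is.null(msg)) return(msg)
  if (any(object@data$rho_um < 0, na.rm = TRUE))
    return("neck radius must be non-negative")
  if (!is.na(object@R0_um)) {
    r0 <- sqrt((object@A1_um2 + object@A2_um2) / (2 * pi))
    if (abs(object@R0_um - r0) > 1e-6 * max(1, r0))
      return("R0 must equal sqrt((A1+A2)/(2*pi))")
  }
  TRUE
})

#' CountSeries: cluster counts per day for one condition
#'
#' @slot data data.frame with columns \code{t_day}, \code{N},
#'   \code{condition}.
#' @slot onsetDay onset used when the series has been shifted (NA before
#'   alignment).
#' @export
setClass("CountSeries",
  representation(data = "data.frame", onsetDay = "numeric"),
  prototype(data = data.frame(t_day = numeric(0), N = numeric(0),
                              condition = character(0)),
            onsetDay = NA_real_))

setValidity("CountSeries", function(object) {
  msg <- .checkCols(object@data, c("t_day", "N", "condition"),
                    "CountSeries@data")
  if (!is.null(msg)) return(msg)
  d <- object@data
  if (any(d$N < 0, na.rm = TRUE)) return("counts must be non-negative")
  for (cond in unique(d$condition)) {
    tt <- d$t_day[d$condition == cond]
    if (is.unsorted(tt, strictly = TRUE))
      return(sprintf("times must be strictly increasing within '%s'", cond))
  }
  TRUE
})

#' OrientationField: nematic angles with optional coherence weights
#'
#' @slot theta angles in radians, stored modulo pi in \code{[0, pi)}.
#' @slot weight coherence weights in \code{[0, 1]} (length 0 for unweighted).
#' @slot reference reference direction in radians (default 0, image
#'   horizontal).
#' @export
setClass("OrientationField",
  representation(theta = "numeric", weight = "numeric",
                 reference = "numeric"),
  prototype(theta = numeric(0), weight = numeric(0), reference = 0))

setValidity("OrientationField", function(object) {
  if (any(object@theta < 0 | object@theta >= pi))
    return("theta must be stored in [0, pi)")
  if (length(object@weight) &&
      length(object@weight) != length(object@theta))
    return("weight must be empty or match theta in length")
  if (length(object@weight) &&
      any(object@weight < 0 | object@weight > 1))
    return("weights must lie in [0, 1]")
  TRUE
})

#' VelocityField: PIV displacement grid and summaries
#'
#' @slot data data.frame with columns \code{x_px}, \code{y_px}, \code{u},
#'   \code{v} (displacements in px/frame) and logical \code{valid}.
#' @slot dt_s frame interval in seconds.
#' @slot pixelSize um per pixel.
#' @slot vrms_um_h root-mean-square speed over valid vectors (NA until
#'   \code{filterVelocityField} has been applied).
#' @slot removedFraction fraction of vectors invalidated by the outlier
#'   filter.
#' @export
setClass("VelocityField",
  representation(data = "data.frame", dt_s = "numeric", pixelSize = "numeric",
                 vrms_um_h = "numeric", removedFraction = "numeric"),
  prototype(data = data.frame(x_px = numeric(0), y_px = numeric(0),
                              u = numeric(0), v = numeric(0),
                              valid = logical(0)),
            dt_s = NA_real_, pixelSize = NA_real_, vrms_um_h = NA_real_,
            removedFraction = NA_real_))

setValidity("VelocityField", function(object) {
  msg <- .checkCols(object@data, c("x_px", "y_px", "u", "v", "valid"),
                    "VelocityField@data")
  if (!is.null(msg)) return(msg)
  if (!is.na(object@vrms_um_h) && object@vrms_um_h < 0)
    return("vrms must be non-negative")
  TRUE
})

# ---- fit result classes ----------------------------------------------------

#' HoleFit: exponential-saturation fit of hole width
#'
#' Result of fitting \eqn{a(t) = a_{max}[1 - \exp(-Ct)]}.
#'
#' @slot aMax_um saturation width (um).
#' @slot C_per_s rate constant (1/s); \code{1/C_per_s} is the stretching time.
#' @slot se named numeric standard errors (bootstrap), entries
#'   \code{aMax_um}, \code{C_per_s}.
#' @slot residualSD_um residual standard deviation (um).
#' @slot fitted data.frame \code{t_s}, \code{width_um}, \code{fit_um},
#'   \code{resid_um}.
#' @slot nBoot number of bootstrap resamples used for the SEs.
#' @export
setClass("HoleFit",
  representation(aMax_um = "numeric", C_per_s = "numeric", se = "numeric",
                 residualSD_um = "numeric", fitted = "data.frame",
                 nBoot = "integer"))

setValidity("HoleFit", function(object) {
  if (object@aMax_um <= 0) return("aMax must be positive")
  if (object@C_per_s <= 0) return("C must be positive")
  TRUE
})

#' RoundingFit: capillary velocity from anisotropy decay
#'
#' Result of regressing \eqn{\ln(\epsilon/\epsilon_0)} on the cumulative
#' \eqn{\int dt/r} per cluster; slope \eqn{s} gives
#' \eqn{\gamma/\eta = -(56/15)\, s}.
#'
#' @slot gammaOverEta_m_s pooled capillary velocity (m/s).
#' @slot se_m_s standard error of the pooled estimate.
#' @slot perTrack data.frame with one row per cluster: \code{track},
#'   \code{slope_m_s}, \code{se_m_s}, \code{gammaOverEta_m_s}, \code{eps0},
#'   \code{r2}, \code{nUsed}.
#' @export
setClass("RoundingFit",
  representation(gammaOverEta_m_s = "numeric", se_m_s = "numeric",
                 perTrack = "data.frame"))

setValidity("RoundingFit", function(object) {
  if (object@gammaOverEta_m_s <= 0)
    return("gamma/eta must be positive")
  TRUE
})

#' FusionFit: Frenkel sintering fit of neck growth
#'
#' Result of the through-origin regression of \eqn{\rho^2/R_0} on time since
#' first contact; the slope is the capillary velocity \eqn{\gamma/\eta}.
#'
#' @slot gammaOverEta_m_s capillary velocity (m/s).
#' @slot se_m_s regression standard error of the slope.
#' @slot R0_um effective initial radius (um).
#' @slot plateau_um plateau neck radius (median of the last quartile).
#' @slot growthIdx integer indices of the frames used (growth phase).
#' @slot r2 coefficient of determination of the through-origin regression.
#' @export
setClass("FusionFit",
  representation(gammaOverEta_m_s = "numeric", se_m_s = "numeric",
                 R0_um = "numeric", plateau_um = "numeric",
                 growthIdx = "integer", r2 = "numeric"))

setValidity("FusionFit", function(object) {
  if (object@gammaOverEta_m_s <= 0) return("gamma/eta must be positive")
  if (object@plateau_um > object@R0_um * 1.05 + 1e-9)
    return("plateau exceeds R0 beyond tolerance")
  TRUE
})

#' PopulationFit: cluster population dynamics fit
#'
#' Result of fitting \eqn{dN/dt = p_1 - \alpha(t) p_2 N},
#' \eqn{\alpha(t)=\min(t/t_s, 1)}, by least squares with an RK4 forward
#' model.
#'
#' @slot p1 cluster formation rate (clusters/day).
#' @slot p2 relative cluster reduction rate (1/day).
#' @slot ts_day stabilization time of the fusion-rate ramp (day).
#' @slot se named numeric bootstrap standard errors.
#' @slot residualSD residual standard deviation (clusters).
#' @slot plateau long-time plateau \eqn{p_1/p_2}.
#' @export
setClass("PopulationFit",
  representation(p1 = "numeric", p2 = "numeric", ts_day = "numeric",
                 se = "numeric", residualSD = "numeric", plateau = "numeric"))

setValidity("PopulationFit", function(object) {
  if (object@p1 <= 0 || object@p2 <= 0 || object@ts_day <= 0)
    return("all parameters must be positive")
  if (abs(object@plateau - object@p1 / object@p2) > 1e-9 * object@plateau)
    return("plateau must equal p1/p2")
  TRUE
})
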