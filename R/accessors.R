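#' Extract the underlying per-frame table of a series object
#'
#' @param x a \code{ShapeTrack}, \code{HoleSeries}, \code{FusionSeries},
#'   \code{CountSeries} or \code{VelocityField}.
#' @return a data.frame (a copy; series objects are immutable).
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))

#' @rdname seriesData
#' @export
setMethod("seriesData", "ShapeTrack", function(x) x@data)
#' @rdname seriesData
#' @export
setMethod("seriesData", "HoleSeries", function(x) x@data)
#' @rdname seriesData
#' @export
setMethod("seriesData", "FusionSeries", function(x) x@data)
#' @rdname seriesData
#' @export
setMethod("seriesData", "CountSeries", function(x) x@data)
#' @rdname seriesData
#' @export
setMethod("seriesData", "VelocityField", function(x) x@data)

#' Capillary velocity accessor
#'
#' Returns the fitted surface-tension-to-viscosity ratio \eqn{\gamma/\eta}
#' in m/s from a rounding or fusion fit.
#'
#' @param x a \code{RoundingFit} or \code{FusionFit}.
#' @return numeric scalar (m/s).
#' @export
setGeneric("gammaOverEta", function(x) standardGeneric("gammaOverEta"))

#' @rdname gammaOverEta
#' @export
setMethod("gammaOverEta", "RoundingFit", function(x) x@gammaOverEta_m_s)
#' @rdname gammaOverEta
#' @export
setMethod("gammaOverEta", "FusionFit", function(x) x@gammaOverEta_m_s)

#' @describeIn HoleFit-class fitted parameters as a named vector.
#' @param object a \code{HoleFit}.
#' @export
setMethod("coef", "HoleFit", function(object)
  c(aMax_um = object@aMax_um, C_per_s = object@C_per_s))

#' @describeIn PopulationFit-class fitted parameters as a named vector.
#' @param object a \code{PopulationFit}.
#' @export
setMethod("coef", "PopulationFit", function(object)
  c(p1 = object@p1, p2 = object@p2, ts_day = object@ts_day))

#' Object identifier of a track
#' @param x a \code{ShapeTrack}.
#' @return integer id.
#' @export
setGeneric("objectId", function(x) standardGeneric("objectId"))
#' @rdname objectId
#' @export
setMethod("objectId", "ShapeTrack", function(x) x@objectId)

#' Root-mean-square speed of a filtered velocity field
#' @param x a \code{VelocityField} after \code{filterVelocityField}.
#' @return numeric scalar in um/h.
#' @export
setGeneric("vrms", function(x) standardGeneric("vrms"))
#' @rdname vrms
#' @export
setMethod("vrms", "VelocityField", function(x) x@vrms_um_h)

# ---- show methods ----------------------------------------------------------

setMethod("show", "ShapeTrack", function(object) {
  d <- object@data
  cat(sprintf("ShapeTrack (object %d): %d frames", object@objectId, nrow(d)))
  if (nrow(d))
    cat(sprintf(", t = [%.0f, %.0f] s, circ %.3f -> %.3f",
                min(d$t_s), max(d$t_s), d$circ[1], d$circ[nrow(d)]))
  cat("\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "HoleSeries", function(object) {
  d <- object@data
  cat(sprintf("HoleSeries: %d frames, %d tip-profile points\n",
              nrow(d), nrow(object@profile)))
  if (nrow(d))
    cat(sprintf("  width %.1f -> %.1f um over %.0f s\n",
                d$width_um[1], d$width_um[nrow(d)], diff(range(d$t_s))))
})

setMethod("show", "FusionSeries", function(object) {
  cat(sprintf("FusionSeries: %d frames, R0 = %.1f um\n",
              nrow(object@data), object@R0_um))
})

setMethod("show", "CountSeries", function(object) {
  d <- object@data
  cat(sprintf("CountSeries: %d samples, condition(s) %s\n", nrow(d),
              paste(unique(d$condition), collapse = ", ")))
  if (!is.na(object@onsetDay))
    cat(sprintf("  aligned, onset day %.1f\n", object@onsetDay))
})

setMethod("show", "OrientationField", function(object) {
  cat(sprintf("OrientationField: %d angles%s\n", length(object@theta),
              if (length(object@weight)) " (coherence-weighted)" else ""))
})

setMethod("show", "VelocityField", function(object) {
  d <- object@data
  cat(sprintf("VelocityField: %d vectors (%d valid)\n",
              nrow(d), sum(d$valid)))
  if (!is.na(object@vrms_um_h))
    cat(sprintf("  V_rms = %.2f um/h, %.1f%% removed\n",
                object@vrms_um_h, 100 * object@removedFraction))
})

setMethod("show", "HoleFit", function(object) {
  cat(sprintf(
    "HoleFit: a_max = %.1f um (SE %.2g), C = %.3g /s (SE %.2g)\n",
    object@aMax_um, object@se["aMax_um"], object@C_per_s,
    object@se["C_per_s"]))
  cat(sprintf("  stretching time 1/C = %.0f s, residual SD %.2f um\n",
              1 / object@C_per_s, object@residualSD_um))
})

setMethod("show", "RoundingFit", function(object) {
  cat(sprintf("RoundingFit: gamma/eta = %.3g m/s (SE %.2g), %d cluster(s)\n",
              object@gammaOverEta_m_s, object@se_m_s,
              nrow(object@perTrack)))
})

setMethod("show", "FusionFit", function(object) {
  cat(sprintf(
    "FusionFit: gamma/eta = %.3g m/s, R0 = %.1f um, plateau %.1f um\n",
    object@gammaOverEta_m_s, object@R0_um, object@plateau_um))
})

setMethod("show", "PopulationFit", function(object) {
  cat(sprintf(
    "PopulationFit: p1 = %.2f /day, p2 = %.3f /day, t_s = %.2f day\n",
    object@p1, object@p2, object@ts_day))
  cat(sprintf("  plateau p1/p2 = %.2f clusters\n", object@plateau))
})
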