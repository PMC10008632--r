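# CSV dialects (unit-suffixed column names), JSON configuration with
# defaulting and strict key validation, and the run manifest.

#' Write a series object to CSV
#'
#' Column schemas: hole \code{(t_s, width_um)}; track \code{(track, t_s,
#' area_um2, perimeter_um, circ, major_um, minor_um, eps, r_um, cx_um,
#' cy_um)}; fusion \code{(t_s, rho_um)} plus constant columns
#' \code{A1_um2, A2_um2}; counts \code{(t_day, N, condition)}.
#'
#' @param x a series object or a list of \code{ShapeTrack} /
#'   \code{FusionSeries}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
setGeneric("writeSeriesCSV", function(x, path) standardGeneric("writeSeriesCSV"))

#' @rdname writeSeriesCSV
#' @export
setMethod("writeSeriesCSV", "HoleSeries", function(x, path) {
  utils::write.csv(x@data, path, row.names = FALSE)
  invisible(path)
})

#' @rdname writeSeriesCSV
#' @export
setMethod("writeSeriesCSV", "ShapeTrack", function(x, path) {
  utils::write.csv(cbind(track = x@objectId, x@data), path,
                   row.names = FALSE)
  invisible(path)
})

#' @rdname writeSeriesCSV
#' @export
setMethod("writeSeriesCSV", "FusionSeries", function(x, path) {
  utils::write.csv(cbind(x@data, A1_um2 = x@A1_um2, A2_um2 = x@A2_um2),
                   path, row.names = FALSE)
  invisible(path)
})

#' @rdname writeSeriesCSV
#' @export
setMethod("writeSeriesCSV", "CountSeries", function(x, path) {
  utils::write.csv(x@data, path, row.names = FALSE)
  invisible(path)
})

#' @rdname writeSeriesCSV
#' @export
setMethod("writeSeriesCSV", "list", function(x, path) {
  if (!length(x)) stop("empty list")
  if (is(x[[1]], "ShapeTrack")) {
    df <- do.call(rbind, lapply(x, function(tr)
      cbind(track = tr@objectId, tr@data)))
  } else if (is(x[[1]], "FusionSeries")) {
    df <- do.call(rbind, lapply(seq_along(x), function(i)
      cbind(pair = i, x[[i]]@data, A1_um2 = x[[i]]@A1_um2,
            A2_um2 = x[[i]]@A2_um2)))
  } else if (is(x[[1]], "CountSeries")) {
    df <- do.call(rbind, lapply(x, function(s) s@data))
  } else stop("unsupported list element class")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
})

#' Read a hole-width CSV
#' @param path CSV with columns \code{t_s}, \code{width_um}.
#' @return a \code{HoleSeries}.
#' @export
readHoleSeries <- function(path) {
  d <- utils::read.csv(path)
  new("HoleSeries", data = d[, c("t_s", "width_um")])
}

#' Read a morphometric track CSV
#' @param path CSV in the track schema (a \code{track} column splits
#'   multiple tracks).
#' @return list of \code{ShapeTrack}.
#' @export
readShapeTracks <- function(path) {
  d <- utils::read.csv(path)
  ids <- if ("track" %in% names(d)) unique(d$track) else 1L
  lapply(ids, function(id) {
    di <- if ("track" %in% names(d)) d[d$track == id, ] else d
    di$track <- NULL
    new("ShapeTrack", objectId = as.integer(id), data = di,
        pixelSize = NA_real_, flags = character(0))
  })
}

#' Read a fusion-neck CSV
#' @param path CSV with \code{t_s}, \code{rho_um} and either constant
#'   \code{A1_um2}/\code{A2_um2} columns or a \code{pair} column splitting
#'   several pairs.
#' @return a \code{FusionSeries} or list of them.
#' @export
readFusionSeries <- function(path) {
  d <- utils::read.csv(path)
  mk <- function(di) new("FusionSeries",
                         data = di[, c("t_s", "rho_um")],
                         A1_um2 = di$A1_um2[1], A2_um2 = di$A2_um2[1],
                         R0_um = sqrt((di$A1_um2[1] + di$A2_um2[1]) /
                                        (2 * pi)))
  if ("pair" %in% names(d))
    return(lapply(split(d, d$pair), mk))
  mk(d)
}

#' Read a cluster-count CSV
#' @param path CSV with \code{t_day}, \code{N}, \code{condition}.
#' @return a \code{CountSeries}.
#' @export
readCountSeries <- function(path) {
  d <- utils::read.csv(path)
  d$condition <- as.character(d$condition)
  new("CountSeries", data = d[, c("t_day", "N", "condition")],
      onsetDay = NA_real_)
}

# ---- configuration ---------------------------------------------------------

.configDefaults <- function(scenario) {
  base <- list(seed = 1L, scenario = scenario, pixel_size = 0.65)
  sc <- switch(scenario,
    hole = list(frame_interval_s = 300, params = list(
      aMax_um = 200, C_per_s = 2e-3, noiseSD_um = 5, nFrames = 60L,
      duration_s = 2000)),
    rounding = list(frame_interval_s = 1200, params = list(
      eps0 = -0.4, gammaOverEta_m_s = 1e-8, r0_um = 100,
      axisNoiseSD_um = 2, nFrames = 72L)),
    fusion = list(frame_interval_s = 1200, params = list(
      R1_um = 100, R2_um = 100, gammaOverEta_m_s = 2.9e-9,
      noiseSD_um = 2, nFrames = 48L)),
    counts = list(params = list(
      p1 = 50, p2 = 1.5, ts_day = 8, horizon_day = 14,
      noise = "poisson", onsetDelay_day = 0)),
    orientation = list(params = list(n = 1000L, kappa = 1, mu = 0)),
    speckle = list(frame_interval_s = 300, params = list(
      shape = c(256L, 256L), u_px = 0, v_px = 0)),
    stop(sprintf("unknown scenario '%s'", scenario)))
  c(base, sc)
}

#' Load and validate a simulation configuration
#'
#' Reads a JSON document, fills scenario defaults, rejects unknown keys
#' (reported with their key path) and validates ranges: positive lengths and
#' times, \code{kappa >= 0}, \code{|eps0| < 1}.
#'
#' @param path JSON file with at least \code{\{"seed": ..., "scenario":
#'   ...\}}.
#' @return validated configuration list (seed, scenario, pixel_size,
#'   frame_interval_s where applicable, params).
#' @export
loadConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$scenario)) stop("config: missing required key 'scenario'")
  if (is.null(cfg$seed)) stop("config: missing required key 'seed'")
  def <- .configDefaults(cfg$scenario)
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$params)) {
    unknownP <- setdiff(names(cfg$params), names(def$params))
    if (length(unknownP))
      stop("config: unknown key(s): ",
           paste(paste0("params.", unknownP), collapse = ", "))
    def$params[names(cfg$params)] <- cfg$params
    cfg$params <- NULL
  }
  def[names(cfg)] <- cfg
  cfg <- def
  if (!is.null(cfg$pixel_size) && cfg$pixel_size <= 0)
    stop("config: pixel_size must be positive")
  if (!is.null(cfg$frame_interval_s) && cfg$frame_interval_s <= 0)
    stop("config: frame_interval_s must be positive")
  p <- cfg$params
  for (key in c("aMax_um", "C_per_s", "r0_um", "R1_um", "R2_um",
                "gammaOverEta_m_s", "p1", "p2", "ts_day", "horizon_day"))
    if (!is.null(p[[key]]) && p[[key]] <= 0)
      stop(sprintf("config: params.%s must be positive", key))
  if (!is.null(p$kappa) && p$kappa < 0)
    stop("config: params.kappa must be >= 0")
  if (!is.null(p$eps0) && abs(p$eps0) >= 1)
    stop("config: params.eps0 must satisfy |eps0| < 1")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the generator named by a configuration
#'
#' @param cfg a configuration from \code{\link{loadConfig}} (or an
#'   equivalent list).
#' @return the generated series object (or list for speckle pairs).
#' @export
simulateFromConfig <- function(cfg) {
  p <- cfg$params
  switch(cfg$scenario,
    hole = simulateHoleSeries(
      aMax_um = p$aMax_um, C_per_s = p$C_per_s,
      times_s = seq(0, p$duration_s, length.out = p$nFrames),
      noiseSD_um = p$noiseSD_um, seed = cfg$seed),
    rounding = simulateRoundingTrack(
      eps0 = p$eps0, gammaOverEta_m_s = p$gammaOverEta_m_s,
      r0_um = p$r0_um, dt_s = cfg$frame_interval_s, nFrames = p$nFrames,
      axisNoiseSD_um = p$axisNoiseSD_um, seed = cfg$seed),
    fusion = simulateFusionSeries(
      R1_um = p$R1_um, R2_um = p$R2_um,
      gammaOverEta_m_s = p$gammaOverEta_m_s, dt_s = cfg$frame_interval_s,
      nFrames = p$nFrames, noiseSD_um = p$noiseSD_um, seed = cfg$seed),
    counts = simulateCountSeries(
      p1 = p$p1, p2 = p$p2, ts_day = p$ts_day,
      horizon_day = p$horizon_day, noise = p$noise,
      onsetDelay_day = p$onsetDelay_day, seed = cfg$seed),
    orientation = simulateOrientationAngles(
      n = p$n, kappa = p$kappa, mu = p$mu, seed = cfg$seed),
    speckle = simulateSpecklePair(
      shape = p$shape, displacement = c(p$u_px, p$v_px), seed = cfg$seed),
    stop(sprintf("unknown scenario '%s'", cfg$scenario)))
}
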