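#' Run the full synthetic-recovery suite
#'
#' Generates one default synthetic dataset per modality, runs every analysis
#' stage (hole-width fit, rounding fit, Frenkel fusion fit, population fit,
#' order parameter, PIV round trip), writes CSV/JSON results plus a summary
#' table comparing recovered and ground-truth parameters, and records a run
#' manifest. A failing stage is recorded and the suite continues.
#'
#' @param outDir writable output directory (created if absent).
#' @param seed master seed; the run is fully deterministic given it.
#' @param nTracks number of rounding tracks (default 7, the sample size
#'   behind the reported rounding estimate).
#' @param nPairs number of fusion pairs (default 3).
#' @param nBoot bootstrap resamples for the hole fit SEs.
#' @return invisibly, a list with \code{summary} (data.frame) and
#'   \code{manifest}.
#' @export
runRecoverySuite <- function(outDir, seed = 1, nTracks = 7L, nPairs = 3L,
                          nBoot = 200L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  rows <- list(); warnings <- character(0); timings <- list()
  addRow <- function(stage, quantity, truth, recovered) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, quantity = quantity, truth = truth,
      recovered = recovered,
      rel_error = abs(recovered - truth) / abs(truth))
  }
  stage <- function(name, code) {
    st <- Sys.time()
    res <- tryCatch(code, error = function(e) {
      warnings <<- c(warnings, sprintf("stage %s failed: %s", name,
                                       conditionMessage(e)))
      NULL
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    res
  }

  stage("hole", {
    hs <- simulateHoleSeries(noiseSD_um = 5, seed = seed)
    writeSeriesCSV(hs, file.path(outDir, "hole.csv"))
    fit <- fitHoleWidth(hs, nBoot = nBoot, seed = seed)
    addRow("hole", "aMax_um", 200, fit@aMax_um)
    addRow("hole", "C_per_s", 2e-3, fit@C_per_s)
    consts <- deriveConstants(fit)
    jsonlite::write_json(
      list(aMax_um = fit@aMax_um, C_per_s = fit@C_per_s,
           se = as.list(fit@se), residualSD_um = fit@residualSD_um,
           k_Pa_s_m = consts$k_Pa_s_m, seed = seed),
      file.path(outDir, "hole_fit.json"), auto_unbox = TRUE, digits = NA)
  })

  stage("rounding", {
    tracks <- lapply(seq_len(nTracks), function(i)
      simulateRoundingTrack(axisNoiseSD_um = 2, seed = seed + i,
                            objectId = i))
    writeSeriesCSV(tracks, file.path(outDir, "tracks.csv"))
    fit <- fitRounding(tracks)
    addRow("rounding", "gammaOverEta_m_s", 1e-8, gammaOverEta(fit))
    jsonlite::write_json(
      list(gammaOverEta_m_s = gammaOverEta(fit), se_m_s = fit@se_m_s,
           nTracks = nrow(fit@perTrack), seed = seed),
      file.path(outDir, "rounding_fit.json"), auto_unbox = TRUE,
      digits = NA)
  })

  stage("fusion", {
    pairs <- lapply(seq_len(nPairs), function(i)
      simulateFusionSeries(noiseSD_um = 2, seed = seed + i))
    writeSeriesCSV(pairs, file.path(outDir, "fusion.csv"))
    pool <- poolFrenkel(pairs)
    addRow("fusion", "gammaOverEta_m_s", 2.9e-9, pool$mean_m_s)
    addRow("fusion", "plateau_um", 100, pool$fits[[1]]@plateau_um)
    jsonlite::write_json(
      list(gammaOverEta_m_s = pool$mean_m_s, sd_m_s = pool$sd_m_s,
           n = pool$n, seed = seed),
      file.path(outDir, "fusion_fit.json"), auto_unbox = TRUE, digits = NA)
  })

  stage("population", {
    conds <- list(HD = 0, MD = 3, LD = 3)
    series <- lapply(names(conds), function(cn)
      simulateCountSeries(noise = "poisson", onsetDelay_day = conds[[cn]],
                          condition = cn,
                          seed = seed + match(cn, names(conds))))
    writeSeriesCSV(series, file.path(outDir, "counts.csv"))
    shifted <- alignOnsets(series)
    fit <- fitPopulation(shifted, nBoot = 0)
    addRow("population", "p1", 50, fit@p1)
    addRow("population", "p2", 1.5, fit@p2)
    addRow("population", "ts_day", 8, fit@ts_day)
    jsonlite::write_json(
      list(p1 = fit@p1, p2 = fit@p2, ts_day = fit@ts_day,
           plateau = fit@plateau, seed = seed),
      file.path(outDir, "population_fit.json"), auto_unbox = TRUE,
      digits = NA)
  })

  stage("orientation", {
    targetQ <- 0.87
    kap <- kappaForOrder(targetQ)
    of <- simulateOrientationAngles(n = 2000L, kappa = kap, seed = seed)
    addRow("orientation", "Q_high_density", targetQ, orderParameter(of))
  })

  stage("piv", {
    shift <- c(3.2, -1.7)
    sp <- simulateSpecklePair(displacement = shift, seed = seed)
    vf <- pivPair(sp$frame1, sp$frame2)
    vf <- filterVelocityField(vf)
    d <- seriesData(vf)
    addRow("piv", "u_px", shift[1], stats::median(d$u[d$valid]))
    addRow("piv", "v_px", shift[2], stats::median(d$v[d$valid]))
  })

  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(outDir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    tool = "DewetDynamics",
    version = as.character(utils::packageVersion("DewetDynamics")),
    seed = seed,
    config = list(nTracks = nTracks, nPairs = nPairs, nBoot = nBoot),
    outputs = list.files(outDir),
    timings_s = timings,
    warnings = warnings)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summary, manifest = manifest))
}
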