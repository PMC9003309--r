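# End-to-end pipeline: simulate -> calibrate -> estimate (with drift
# correction) -> angles -> evaluate, driven by a YAML configuration.

pipelineDefaults <- function() {
  list(
    seed = 1,
    keyframeRate = 20,
    nWindows = 60,
    mStar = 0.05,
    driftCorrection = TRUE,
    noise = list(sigmaGyro = 0.01, sigmaAccel = 0.1, sigmaJc = 0.01,
                 sigmaHingeKnee = 0.05, sigmaHingeHip = 0.3,
                 sigmaHingeAnkle = 0.3, sigmaBiasGyro = 0.02,
                 sigmaBiasAccel = 0.2, gravity = 9.81),
    simulate = NULL,
    paths = list(outputDir = "walkimu_out", calibrationDir = NULL,
                 walkingDir = NULL, referenceAngles = NULL))
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, checks every key against the schema and
#' fills defaults (keyframe rate 20 Hz, 60 windows, m* = 0.05 deg/s).
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  def <- pipelineDefaults()
  checkKeys <- function(x, ref, prefix = "") {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown))
      stop("config error: unknown key '", prefix, unknown[1], "'")
  }
  checkKeys(raw, def)
  for (sub in c("noise", "paths", "simulate"))
    if (!is.null(raw[[sub]])) {
      ref <- if (sub == "simulate")
        list(kind = NULL, walkingDuration = 30, calibrationDuration = 60,
             fs = 200, cadence = 100, degenerate1dof = FALSE,
             softTissueStanceDeg = 0, softTissueSwingDeg = 0)
      else def[[sub]]
      checkKeys(raw[[sub]], ref, paste0(sub, "."))
    }
  cfg <- utils::modifyList(def, raw)
  num1 <- function(x, nm, min = NULL) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop("config error: '", nm, "' must be a single number")
    if (!is.null(min) && x < min)
      stop("config error: '", nm, "' must be >= ", min)
  }
  num1(cfg$seed, "seed")
  num1(cfg$keyframeRate, "keyframeRate", 1)
  num1(cfg$nWindows, "nWindows", 1)
  num1(cfg$mStar, "mStar", 0)
  if (cfg$mStar <= 0) stop("config error: 'mStar' must be > 0")
  if (!is.logical(cfg$driftCorrection))
    stop("config error: 'driftCorrection' must be true/false")
  for (nm in names(cfg$noise)) num1(cfg$noise[[nm]], paste0("noise.", nm))
  cfg
}

readArrayDir <- function(dir) {
  recs <- lapply(imuPlacements(), function(id)
    readImuCsv(file.path(dir, paste0(id, ".csv")), id))
  assembleArray(recs)
}

writeArrayDir <- function(array, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in imuPlacements())
    writeImuCsv(recordings(array)[[id]], file.path(dir, paste0(id, ".csv")))
  invisible(dir)
}

#' Write / read a calibration as JSON
#'
#' Vectors in meters, axes unit-norm, covariances row-major.
#' @param calib a [CalibrationParameters-class]. @param path file path.
#' @export
writeCalibrationJson <- function(calib, path) {
  obj <- list(
    jointCenters = lapply(calib@jointCenters, as.numeric),
    hingeAxes = lapply(calib@hingeAxes, as.numeric),
    covariances = lapply(calib@covariances, function(C) as.numeric(t(C))),
    notes = calib@notes)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationJson
#' @export
readCalibrationJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- lapply(obj$covariances, function(v) matrix(v, 3, 3, byrow = TRUE))
  CalibrationParameters(
    jointCenters = lapply(obj$jointCenters, as.numeric),
    hingeAxes = lapply(obj$hingeAxes, as.numeric),
    covariances = covs,
    notes = as.character(unlist(obj$notes)))
}

writeAnglesCsv <- function(series, path) {
  d <- data.frame(t = series@t, fe = series@fe, aa = series@aa,
                  ie = series@ie)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Run the full estimation pipeline
#'
#' Executes: obtain calibration and walking recordings (simulated from the
#' built-in gait generator, or read from per-sensor CSV directories), run
#' the self-calibration, use its hip-center estimates as priors for the
#' windowed walking estimation with drift correction, derive hip and knee
#' angles, and - when a reference is available - compute comparison
#' metrics and the gait-phase error profile. All artifacts are written
#' under `config$paths$outputDir`.
#'
#' @param config a validated configuration (from [validateConfig()]) or a
#'   path to a YAML file.
#' @return invisibly, a list with the artifact paths and (if computed) the
#'   metrics.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- validateConfig(config)
  out <- config$paths$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- do.call(noiseConfig, config$noise)
  simulated <- !is.null(config$simulate)
  refAngles <- NULL
  events <- NULL
  if (simulated) {
    sim <- config$simulate
    ns <- noiseSpec(sigmaGyro = config$noise$sigmaGyro,
                    sigmaAccel = config$noise$sigmaAccel, seed = config$seed)
    calTrial <- generateTrial("calibration", seed = config$seed,
                              duration = sim$calibrationDuration %||% 60,
                              fs = sim$fs %||% 200, noise = ns)
    walkTrial <- generateTrial("walking", seed = config$seed + 1,
                               duration = sim$walkingDuration %||% 30,
                               fs = sim$fs %||% 200,
                               cadence = sim$cadence %||% 100,
                               degenerate1dof = isTRUE(sim$degenerate1dof),
                               noise = ns)
    if ((sim$softTissueStanceDeg %||% 0) != 0 ||
        (sim$softTissueSwingDeg %||% 0) != 0)
      walkTrial <- injectSoftTissue(walkTrial, sim$softTissueStanceDeg %||% 0,
                                    sim$softTissueSwingDeg %||% 0)
    calArray <- sensorArray(calTrial)
    walkArray <- sensorArray(walkTrial)
    refAngles <- truthAngles(walkTrial)
    events <- gaitEvents(walkTrial)
  } else {
    if (is.null(config$paths$calibrationDir))
      stop("missing calibration input: walking estimation requires priors ",
           "from a calibration task")
    calArray <- readArrayDir(config$paths$calibrationDir)
    walkArray <- readArrayDir(config$paths$walkingDir)
  }
  message("walkimu: running self-calibration ...")
  calib <- runCalibration(calArray, cfg, config$keyframeRate)
  calibPath <- file.path(out, "calibration.json")
  writeCalibrationJson(calib, calibPath)
  priors <- priorsFromCalibration(calib)
  message("walkimu: estimating walking windows ...")
  sol <- runWalking(walkArray, priors, cfg, nWindows = config$nWindows,
                    keyframeRate = config$keyframeRate,
                    driftCorrection = isTRUE(config$driftCorrection),
                    mStar = config$mStar, verbose = TRUE)
  ha <- hipAngles(sol)
  ka <- kneeAngles(sol)
  anglePaths <- character()
  for (nm in names(c(ha, ka))) {
    p <- file.path(out, paste0("angles_", nm, ".csv"))
    writeAnglesCsv(c(ha, ka)[[nm]], p)
    anglePaths[nm] <- p
  }
  artifacts <- list(calibration = calibPath, angles = anglePaths)
  metrics <- NULL
  if (!is.null(config$paths$referenceAngles) && !simulated) {
    ref <- utils::read.csv(config$paths$referenceAngles)
    refAngles <- list(knee_r = JointAngleSeries(ref$t, ref$fe, 0 * ref$t,
                                                0 * ref$t, "knee", "right"))
  }
  if (!is.null(refAngles)) {
    metrics <- evaluateAgainstReference(c(ha, ka), refAngles, out)
    artifacts$metrics <- file.path(out, "metrics.json")
    artifacts$profile <- file.path(out, "soft_tissue_profile.csv")
  }
  invisible(list(artifacts = artifacts, metrics = metrics,
                 solution = sol, calibration = calib))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# compare estimated angles with a reference sampled on the same raw
# timebase; reference series are subsampled at the estimate's keyframes
evaluateAgainstReference <- function(est, ref, outDir) {
  metrics <- list()
  profile <- NULL
  for (nm in names(est)) {
    if (is.null(ref[[nm]])) next
    e <- est[[nm]]
    r <- ref[[nm]]
    idx <- match(round(e@t, 9), round(r@t, 9))
    if (any(is.na(idx))) next
    for (ch in c("fe", "aa", "ie")) {
      cmp <- compareSeries(angleChannel(e, ch), angleChannel(r, ch)[idx],
                           joint = e@joint, side = e@side, channel = ch)
      metrics[[paste0(nm, "_", ch)]] <-
        cmp[c("absoluteRmse", "relativeRmse", "peakError", "meanOffset")]
    }
    if (e@joint == "knee") {
      cyc <- try(detectCycles(angleChannel(r, "fe")[idx],
                              fs = 1 / diff(e@t[1:2])), silent = TRUE)
      if (!inherits(cyc, "try-error")) {
        prof <- softTissueProfile(angleChannel(e, "fe"),
                                  angleChannel(r, "fe")[idx], cyc)
        metrics[[paste0(nm, "_stance_mean")]] <- prof$stanceMean
        metrics[[paste0(nm, "_swing_mean")]] <- prof$swingMean
        if (is.null(profile))
          profile <- data.frame(phase = prof$binCenters,
                                meanError = prof$meanError, joint = nm)
        else
          profile <- rbind(profile,
                           data.frame(phase = prof$binCenters,
                                      meanError = prof$meanError,
                                      joint = nm))
      }
    }
  }
  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(profile))
    utils::write.csv(profile, file.path(outDir, "soft_tissue_profile.csv"),
                     row.names = FALSE)
  metrics
}
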