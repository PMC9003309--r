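# S4 containers for the estimation pipeline.

#' Required sensor placements
#'
#' The seven body-worn sensor placements the pipeline expects: one on the
#' sacrum/lumbar region and one on each thigh, shank and foot.
#' @export
imuPlacements <- function() {
  c("lumbar", "thigh_r", "thigh_l", "shank_r", "shank_l", "foot_r", "foot_l")
}

#' Names of the six modelled joints
#' @export
jointNames <- function() {
  c("hip_r", "hip_l", "knee_r", "knee_l", "ankle_r", "ankle_l")
}

# joint -> (proximal sensor, distal sensor)
jointSensors <- function(joint) {
  switch(joint,
    hip_r   = c("lumbar",  "thigh_r"),
    hip_l   = c("lumbar",  "thigh_l"),
    knee_r  = c("thigh_r", "shank_r"),
    knee_l  = c("thigh_l", "shank_l"),
    ankle_r = c("shank_r", "foot_r"),
    ankle_l = c("shank_l", "foot_l"),
    stop("unknown joint: ", joint))
}

#' Names of the twelve sensor-to-joint-center calibration vectors
#'
#' One vector per (joint, flanking sensor) pair, expressed in that sensor's
#' frame; `<joint>_prox` lives in the proximal sensor frame (the lumbar
#' sensor for the hips), `<joint>_dist` in the distal one.
#' @export
jointCenterNames <- function() {
  as.vector(vapply(jointNames(), function(j) paste0(j, c("_prox", "_dist")),
                   character(2)))
}

#' Names of the twelve hinge-axis calibration vectors
#' @export
hingeAxisNames <- function() jointCenterNames()

#' The four hip-connected joint-center vector names
#'
#' The vectors tied to the two hip centers (lumbar and thigh sides of both
#' hips); these receive Gaussian priors during walking estimation.
#' @export
hipConnectedNames <- function() {
  c("hip_r_prox", "hip_r_dist", "hip_l_prox", "hip_l_dist")
}

# ---------------------------------------------------------------------------
# ImuRecording

#' ImuRecording: one sensor's gyroscope/accelerometer streams
#'
#' @slot sensorId placement label, one of [imuPlacements()].
#' @slot t timestamps in seconds, strictly increasing, uniform, t[1] = 0.
#' @slot gyro N x 3 angular rate, rad/s, sensor frame.
#' @slot accel N x 3 specific force, m/s^2, sensor frame (a stationary level
#'   sensor reads +9.81 on its up axis).
#' @slot fs sampling rate, Hz.
#' @export
setClass("ImuRecording",
  representation(sensorId = "character", t = "numeric", gyro = "matrix",
                 accel = "matrix", fs = "numeric"))

setValidity("ImuRecording", function(object) {
  msg <- character()
  if (!object@sensorId %in% imuPlacements())
    msg <- c(msg, sprintf("unknown sensorId '%s'", object@sensorId))
  n <- length(object@t)
  if (n < 2) msg <- c(msg, "recording needs at least 2 samples")
  if (nrow(object@gyro) != n || nrow(object@accel) != n)
    msg <- c(msg, "t, gyro and accel must have equal length")
  if (ncol(object@gyro) != 3 || ncol(object@accel) != 3)
    msg <- c(msg, "gyro and accel must have 3 columns")
  if (!all(is.finite(object@gyro)) || !all(is.finite(object@accel)))
    msg <- c(msg, "non-finite gyro/accel samples")
  if (n >= 2) {
    dt <- diff(object@t)
    if (any(dt <= 0)) msg <- c(msg, "timestamps not strictly increasing")
    else if (max(abs(dt - 1 / object@fs)) >= 1e-6)
      msg <- c(msg, "timestamps not uniform at the stated rate")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ImuRecording
#'
#' @param sensorId placement label.
#' @param t timestamps, seconds. Re-referenced so t[1] = 0.
#' @param gyro,accel N x 3 matrices (rad/s, m/s^2).
#' @param fs sampling rate in Hz; inferred from the median time step when
#'   omitted.
#' @return validated [ImuRecording-class] object.
#' @export
ImuRecording <- function(sensorId, t, gyro, accel, fs = NULL) {
  t <- as.numeric(t)
  if (length(t) < 2) stop("empty-input error: recording needs >= 2 samples")
  if (any(diff(t) <= 0)) stop("sync error: timestamps not strictly increasing")
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  new("ImuRecording", sensorId = sensorId, t = t - t[1],
      gyro = as.matrix(gyro), accel = as.matrix(accel), fs = fs)
}

#' @describeIn ImuRecording number of samples
#' @param x an ImuRecording
#' @export
setMethod("length", "ImuRecording", function(x) length(x@t))

setMethod("show", "ImuRecording", function(object) {
  cat(sprintf("ImuRecording '%s': %d samples @ %.6g Hz (%.2f s)\n",
              object@sensorId, length(object@t), object@fs,
              utils::tail(object@t, 1)))
})

#' Accessors for IMU containers
#'
#' @param x a container object.
#' @name walkimu-accessors
NULL

#' @rdname walkimu-accessors
#' @export
setGeneric("sensorId", function(x) standardGeneric("sensorId"))
#' @rdname walkimu-accessors
#' @export
setMethod("sensorId", "ImuRecording", function(x) x@sensorId)

#' @rdname walkimu-accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname walkimu-accessors
#' @export
setMethod("timestamps", "ImuRecording", function(x) x@t)

#' @rdname walkimu-accessors
#' @export
setGeneric("gyro", function(x) standardGeneric("gyro"))
#' @rdname walkimu-accessors
#' @export
setMethod("gyro", "ImuRecording", function(x) x@gyro)

#' @rdname walkimu-accessors
#' @export
setGeneric("accel", function(x) standardGeneric("accel"))
#' @rdname walkimu-accessors
#' @export
setMethod("accel", "ImuRecording", function(x) x@accel)

#' @rdname walkimu-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname walkimu-accessors
#' @export
setMethod("sampleRate", "ImuRecording", function(x) x@fs)

# ---------------------------------------------------------------------------
# SensorArray

#' SensorArray: the seven synchronized recordings of one trial
#'
#' @slot recordings named list with exactly one [ImuRecording-class] per
#'   placement, all sharing the same timestamp vector.
#' @slot duration trial duration, s.
#' @export
setClass("SensorArray",
  representation(recordings = "list", duration = "numeric"))

setValidity("SensorArray", function(object) {
  msg <- character()
  ids <- unname(vapply(object@recordings, function(r) r@sensorId, character(1)))
  if (!identical(sort(ids), sort(imuPlacements())))
    msg <- c(msg, "need exactly one recording per placement")
  if (!identical(names(object@recordings), ids))
    msg <- c(msg, "recordings must be named by their sensorId")
  if (length(msg) == 0) {
    t0 <- object@recordings[[1]]@t
    for (r in object@recordings)
      if (length(r@t) != length(t0) || max(abs(r@t - t0)) > 1e-6) {
        msg <- c(msg, "recordings are not synchronized"); break
      }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SensorArray", function(object) {
  r <- object@recordings[[1]]
  cat(sprintf("SensorArray: 7 sensors, %d samples @ %.6g Hz (%.1f s)\n",
              length(r@t), r@fs, object@duration))
})

#' @rdname walkimu-accessors
#' @export
setGeneric("recordings", function(x) standardGeneric("recordings"))
#' @rdname walkimu-accessors
#' @export
setMethod("recordings", "SensorArray", function(x) x@recordings)
#' @rdname walkimu-accessors
#' @export
setMethod("timestamps", "SensorArray", function(x) x@recordings[[1]]@t)
#' @rdname walkimu-accessors
#' @export
setMethod("sampleRate", "SensorArray", function(x) x@recordings[[1]]@fs)
#' @describeIn SensorArray number of samples
#' @param x a SensorArray
#' @export
setMethod("length", "SensorArray", function(x) length(x@recordings[[1]]@t))

# ---------------------------------------------------------------------------
# StateTrajectory

#' StateTrajectory: keyframed pose/velocity states of one sensor
#'
#' Orientation quaternions map sensor-frame vectors to the shared
#' gravity-aligned world frame.
#'
#' @slot sensorId placement label.
#' @slot times keyframe times, s, strictly increasing and uniform.
#' @slot q N x 4 unit quaternions (w, x, y, z), sensor -> world.
#' @slot p N x 3 positions, m, world frame.
#' @slot v N x 3 velocities, m/s, world frame.
#' @slot bg,ba constant gyro (rad/s) / accel (m/s^2) bias estimates.
#' @export
setClass("StateTrajectory",
  representation(sensorId = "character", times = "numeric", q = "matrix",
                 p = "matrix", v = "matrix", bg = "numeric", ba = "numeric"))

setValidity("StateTrajectory", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n < 1) msg <- c(msg, "empty trajectory")
  if (nrow(object@q) != n || nrow(object@p) != n || nrow(object@v) != n)
    msg <- c(msg, "times, q, p, v must have matching length")
  if (n >= 2) {
    dt <- diff(object@times)
    if (any(dt <= 0)) msg <- c(msg, "keyframe times not strictly increasing")
    else if (max(abs(dt - dt[1])) > 1e-6)
      msg <- c(msg, "keyframe times not uniform")
  }
  if (n >= 1 && max(abs(rowSums(object@q^2) - 1)) > 1e-6)
    msg <- c(msg, "non-unit quaternions")
  if (max(abs(object@bg)) >= 0.1) msg <- c(msg, "gyro bias out of bounds")
  if (max(abs(object@ba)) >= 1.0) msg <- c(msg, "accel bias out of bounds")
  if (length(msg)) msg else TRUE
})

#' Construct a StateTrajectory
#' @param sensorId placement label.
#' @param times keyframe times (s).
#' @param q N x 4 unit quaternions, sensor -> world.
#' @param p,v N x 3 world positions (m) and velocities (m/s).
#' @param bg,ba constant biases (rad/s, m/s^2).
#' @export
StateTrajectory <- function(sensorId, times, q, p, v,
                            bg = c(0, 0, 0), ba = c(0, 0, 0)) {
  new("StateTrajectory", sensorId = sensorId, times = as.numeric(times),
      q = as.matrix(q), p = as.matrix(p), v = as.matrix(v),
      bg = as.numeric(bg), ba = as.numeric(ba))
}

setMethod("show", "StateTrajectory", function(object) {
  cat(sprintf("StateTrajectory '%s': %d keyframes, %.2f..%.2f s\n",
              object@sensorId, length(object@times),
              object@times[1], utils::tail(object@times, 1)))
})

#' @rdname walkimu-accessors
#' @export
setMethod("timestamps", "StateTrajectory", function(x) x@times)
#' @rdname walkimu-accessors
#' @export
setMethod("sensorId", "StateTrajectory", function(x) x@sensorId)

#' @rdname walkimu-accessors
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))
#' @rdname walkimu-accessors
#' @export
setMethod("orientations", "StateTrajectory", function(x) x@q)

#' @rdname walkimu-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname walkimu-accessors
#' @export
setMethod("positions", "StateTrajectory", function(x) x@p)

#' @rdname walkimu-accessors
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))
#' @rdname walkimu-accessors
#' @export
setMethod("velocities", "StateTrajectory", function(x) x@v)

# ---------------------------------------------------------------------------
# CalibrationParameters

#' CalibrationParameters: static sensor-to-joint geometry
#'
#' @slot jointCenters named list of twelve 3-vectors (m, sensor frame), see
#'   [jointCenterNames()].
#' @slot hingeAxes named list of twelve unit 3-vectors (sensor frame), see
#'   [hingeAxisNames()].
#' @slot covariances named list of 3 x 3 covariance matrices (same names as
#'   jointCenters; may be empty when unavailable).
#' @slot notes character vector of attached diagnostics (e.g. identifiability
#'   warnings).
#' @export
setClass("CalibrationParameters",
  representation(jointCenters = "list", hingeAxes = "list",
                 covariances = "list", notes = "character"))

setValidity("CalibrationParameters", function(object) {
  msg <- character()
  if (!identical(names(object@jointCenters), jointCenterNames()))
    msg <- c(msg, "jointCenters must be named by jointCenterNames()")
  if (!identical(names(object@hingeAxes), hingeAxisNames()))
    msg <- c(msg, "hingeAxes must be named by hingeAxisNames()")
  for (s in object@jointCenters)
    if (length(s) != 3 || sqrt(sum(s^2)) >= 1)
      msg <- c(msg, "joint-center vectors must be 3-vectors shorter than 1 m")
  for (a in object@hingeAxes)
    if (abs(sqrt(sum(a^2)) - 1) > 1e-9)
      msg <- c(msg, "hinge axes must be unit vectors")
  if (length(msg)) unique(msg) else TRUE
})

#' Construct CalibrationParameters
#' @param jointCenters,hingeAxes,covariances named lists (see class slots).
#' @param notes attached diagnostics.
#' @export
CalibrationParameters <- function(jointCenters, hingeAxes,
                                  covariances = list(),
                                  notes = character()) {
  new("CalibrationParameters",
      jointCenters = jointCenters[jointCenterNames()],
      hingeAxes = hingeAxes[hingeAxisNames()],
      covariances = covariances, notes = notes)
}

setMethod("show", "CalibrationParameters", function(object) {
  cat("CalibrationParameters: 12 joint-center vectors, 12 hinge axes\n")
  hip <- object@jointCenters[hipConnectedNames()]
  for (nm in names(hip))
    cat(sprintf("  %-11s [%7.4f %7.4f %7.4f] m\n", nm,
                hip[[nm]][1], hip[[nm]][2], hip[[nm]][3]))
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' @rdname walkimu-accessors
#' @export
setGeneric("jointCenters", function(x) standardGeneric("jointCenters"))
#' @rdname walkimu-accessors
#' @export
setMethod("jointCenters", "CalibrationParameters", function(x) x@jointCenters)

#' @rdname walkimu-accessors
#' @export
setGeneric("hingeAxes", function(x) standardGeneric("hingeAxes"))
#' @rdname walkimu-accessors
#' @export
setMethod("hingeAxes", "CalibrationParameters", function(x) x@hingeAxes)

#' @rdname walkimu-accessors
#' @export
setGeneric("calibNotes", function(x) standardGeneric("calibNotes"))
#' @rdname walkimu-accessors
#' @export
setMethod("calibNotes", "CalibrationParameters", function(x) x@notes)

# ---------------------------------------------------------------------------
# JointAngleSeries

#' JointAngleSeries: 3-DOF joint angle time series
#'
#' Angles are reported in degrees with a bilateral sign convention: positive
#' flexion, adduction and internal rotation on both sides.
#'
#' @slot t times, s.
#' @slot fe,aa,ie flexion/extension, ab/adduction, internal/external, deg.
#' @slot joint one of "hip", "knee", "ankle".
#' @slot side "left" or "right".
#' @slot convention "wu_modified" (hip) or "grood_suntay" (knee/ankle).
#' @export
setClass("JointAngleSeries",
  representation(t = "numeric", fe = "numeric", aa = "numeric",
                 ie = "numeric", joint = "character", side = "character",
                 convention = "character"))

setValidity("JointAngleSeries", function(object) {
  msg <- character()
  n <- length(object@t)
  if (length(object@fe) != n || length(object@aa) != n ||
      length(object@ie) != n)
    msg <- c(msg, "angle channels must match t in length")
  ang <- c(object@fe, object@aa, object@ie)
  if (length(ang) && (!all(is.finite(ang)) || max(abs(ang)) >= 180))
    msg <- c(msg, "angles must be finite and within (-180, 180) deg")
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Construct a JointAngleSeries
#' @param t times (s); @param fe,aa,ie angle channels (deg).
#' @param joint,side,convention labels.
#' @export
JointAngleSeries <- function(t, fe, aa, ie, joint, side,
                             convention = "grood_suntay") {
  new("JointAngleSeries", t = as.numeric(t), fe = as.numeric(fe),
      aa = as.numeric(aa), ie = as.numeric(ie), joint = joint, side = side,
      convention = convention)
}

setMethod("show", "JointAngleSeries", function(object) {
  cat(sprintf("JointAngleSeries %s (%s, %s): %d samples, F/E range [%.1f, %.1f] deg\n",
              object@joint, object@side, object@convention, length(object@t),
              min(object@fe), max(object@fe)))
})

#' Extract one channel of a JointAngleSeries
#' @param x a JointAngleSeries; @param channel "fe", "aa" or "ie".
#' @export
angleChannel <- function(x, channel = c("fe", "aa", "ie")) {
  channel <- match.arg(channel)
  slot(x, channel)
}

#' @rdname walkimu-accessors
#' @export
setMethod("timestamps", "JointAngleSeries", function(x) x@t)

# ---------------------------------------------------------------------------
# Solution

#' Solution: converged estimate for one (or several concatenated) windows
#'
#' @slot trajectories named list of [StateTrajectory-class], one per sensor.
#' @slot calibration [CalibrationParameters-class].
#' @slot cost final objective (0.5 * sum of squared whitened residuals).
#' @slot convergence which stopping criterion fired.
#' @slot iterations LM iterations used.
#' @slot telemetry list of per-window / per-pass diagnostics.
#' @export
setClass("Solution",
  representation(trajectories = "list", calibration = "CalibrationParameters",
                 cost = "numeric", convergence = "character",
                 iterations = "numeric", telemetry = "list"))

setValidity("Solution", function(object) {
  if (!is.finite(object@cost)) return("non-finite cost")
  TRUE
})

setMethod("show", "Solution", function(object) {
  cat(sprintf("Solution: %d sensors, %d keyframes, cost %.6g (%s, %d iters)\n",
              length(object@trajectories),
              length(object@trajectories[[1]]@times), object@cost,
              object@convergence, as.integer(object@iterations)))
})

#' @rdname walkimu-accessors
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))
#' @rdname walkimu-accessors
#' @export
setMethod("trajectories", "Solution", function(x) x@trajectories)

#' @rdname walkimu-accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
#' @rdname walkimu-accessors
#' @export
setMethod("calibration", "Solution", function(x) x@calibration)

#' @rdname walkimu-accessors
#' @export
setGeneric("finalCost", function(x) standardGeneric("finalCost"))
#' @rdname walkimu-accessors
#' @export
setMethod("finalCost", "Solution", function(x) x@cost)

# ---------------------------------------------------------------------------
# SyntheticTrial

#' SyntheticTrial: simulated recordings bundled with their ground truth
#'
#' @slot array [SensorArray-class] of simulated recordings.
#' @slot truthAngles named list of [JointAngleSeries-class] (hips, knees,
#'   ankles) at the raw sampling rate.
#' @slot truthCalibration true [CalibrationParameters-class] implied by the
#'   simulated mounts.
#' @slot truthStates named list of [StateTrajectory-class] per sensor at the
#'   raw rate.
#' @slot events numeric vector of gait-cycle start times (knee maximum
#'   flexion), s; empty for calibration motions.
#' @slot seed integer seed the trial was generated with.
#' @slot meta list of generator settings (kind, cadence, noise, mounts, ...).
#' @export
setClass("SyntheticTrial",
  representation(array = "SensorArray", truthAngles = "list",
                 truthCalibration = "CalibrationParameters",
                 truthStates = "list", events = "numeric", seed = "numeric",
                 meta = "list"))

setMethod("show", "SyntheticTrial", function(object) {
  cat(sprintf("SyntheticTrial (%s, seed %d): %.1f s @ %.6g Hz, %d gait cycles\n",
              if (!is.null(object@meta$kind)) object@meta$kind else "?",
              as.integer(object@seed), object@array@duration,
              sampleRate(object@array), max(0, length(object@events) - 1)))
})

#' @rdname walkimu-accessors
#' @export
setGeneric("sensorArray", function(x) standardGeneric("sensorArray"))
#' @rdname walkimu-accessors
#' @export
setMethod("sensorArray", "SyntheticTrial", function(x) x@array)

#' @rdname walkimu-accessors
#' @export
setGeneric("truthAngles", function(x) standardGeneric("truthAngles"))
#' @rdname walkimu-accessors
#' @export
setMethod("truthAngles", "SyntheticTrial", function(x) x@truthAngles)

#' @rdname walkimu-accessors
#' @export
setGeneric("truthCalibration", function(x) standardGeneric("truthCalibration"))
#' @rdname walkimu-accessors
#' @export
setMethod("truthCalibration", "SyntheticTrial", function(x) x@truthCalibration)

#' @rdname walkimu-accessors
#' @export
setGeneric("truthStates", function(x) standardGeneric("truthStates"))
#' @rdname walkimu-accessors
#' @export
setMethod("truthStates", "SyntheticTrial", function(x) x@truthStates)

#' @rdname walkimu-accessors
#' @export
setGeneric("gaitEvents", function(x) standardGeneric("gaitEvents"))
#' @rdname walkimu-accessors
#' @export
setMethod("gaitEvents", "SyntheticTrial", function(x) x@events)
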