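# Anatomical frame construction and 3-DOF joint angle derivation.
#
# An anatomical frame is a 3 x 3 orthonormal matrix whose ROWS are the
# anatomical basis vectors (x right, y anterior, z proximal) expressed in
# the source sensor frame; it therefore maps sensor-frame coordinates into
# anatomical coordinates. Composed with an estimated sensor orientation
# R_sensor->world, the world orientation of the anatomical frame is
# R_sensor->world %*% t(B).
#
# Hip angles follow a modified ISB (Wu) convention and knee angles the
# Grood-Suntay joint coordinate system; with the proximal direction taken as
# +z in all segments both reduce to the same decomposition: a Cardan
# sequence with e1 = proximal-frame x (medio-lateral, flexion), e3 =
# distal-frame z (longitudinal, axial rotation) and a floating e2
# (ab/adduction). Left-side ab/adduction and axial rotation are mirrored so
# that positive means adduction/internal rotation bilaterally.

#' Construct an orthonormal frame from a right and a proximal axis
#'
#' Rows of the result: the normalized input `x` (kept exactly), the anterior
#' axis `z x x` and the proximal axis `x x (z x x)`, each normalized. The
#' input `z` is thereby corrected for orthonormality while `x` is fixed.
#'
#' @param x right-pointing axis (any length).
#' @param z approximate proximal axis.
#' @return 3 x 3 orthonormal matrix with rows (x, y, z).
#' @export
pcsFromAxes <- function(x, z) {
  nx <- sqrt(sum(x^2)); nz <- sqrt(sum(z^2))
  if (nx < 1e-12 || nz < 1e-12)
    stop("degenerate-axes error: zero-length axis")
  cr <- c(z[2] * x[3] - z[3] * x[2],
          z[3] * x[1] - z[1] * x[3],
          z[1] * x[2] - z[2] * x[1])
  if (sqrt(sum(cr^2)) / (nx * nz) <= 1e-6)
    stop("degenerate-axes error: axes (near-)parallel")
  xh <- x / nx
  yh <- cr / sqrt(sum(cr^2))
  zh <- c(xh[2] * yh[3] - xh[3] * yh[2],
          xh[3] * yh[1] - xh[1] * yh[3],
          xh[1] * yh[2] - xh[2] * yh[1])
  rbind(xh, yh, zh, deparse.level = 0)
}

#' Average vertical (gravity) direction in the lumbar sensor frame
#'
#' The pelvic proximal direction is assumed to be the time-averaged world
#' vertical expressed in the lumbar sensor frame - appropriate for upright
#' gait only. The average is taken over the whole trajectory by default.
#'
#' @param lumbar a [StateTrajectory-class] for the lumbar sensor.
#' @param window optional time window `c(from, to)` in seconds.
#' @return unit 3-vector in the lumbar sensor frame.
#' @export
pelvicVertical <- function(lumbar, window = NULL) {
  keep <- rep(TRUE, length(lumbar@times))
  if (!is.null(window)) {
    keep <- lumbar@times >= window[1] & lumbar@times <= window[2]
    if (!any(keep)) stop("argument error: empty averaging window")
  }
  up <- quatRotate(quatConj(lumbar@q[keep, , drop = FALSE]), c(0, 0, 1))
  unit3(colMeans(up))
}

#' Pelvic anatomical frame in the lumbar sensor frame
#'
#' Built from the estimated inter-hip-center direction (right minus left
#' hip-center vector, both expressed in the lumbar sensor frame) and the
#' average vertical.
#'
#' @param calib a [CalibrationParameters-class].
#' @param v unit vertical from [pelvicVertical()].
#' @return 3 x 3 anatomical frame (rows = axes in lumbar sensor frame).
#' @export
pelvisOrientation <- function(calib, v) {
  sRh <- calib@jointCenters[["hip_r_prox"]]
  sLh <- calib@jointCenters[["hip_l_prox"]]
  d <- sRh - sLh
  if (sqrt(sum(d^2)) <= 0.01)
    stop("degenerate-axes error: hip centers (near-)coincident")
  pcsFromAxes(d / sqrt(sum(d^2)), v)
}

#' Anatomical frames of the thigh, shank and foot sensors
#'
#' Thigh: proximal axis along (hip center - knee center), right axis along
#' the knee hinge axis; shank: (knee - ankle) and the knee axis in the shank
#' frame; foot: the ankle-center direction and the ankle pseudo-axis. All
#' vectors come from the calibration, expressed in each sensor's own frame.
#' The foot frame has no second joint to define its long axis, so its
#' convention is self-consistent rather than anatomical; ankle angles carry
#' no accuracy contract.
#'
#' @param calib a [CalibrationParameters-class].
#' @return named list of 3 x 3 frames for thigh_r/l, shank_r/l, foot_r/l.
#' @export
segmentFrames <- function(calib) {
  jc <- calib@jointCenters; ax <- calib@hingeAxes
  frames <- list()
  for (side in c("r", "l")) {
    hip <- paste0("hip_", side); knee <- paste0("knee_", side)
    ankle <- paste0("ankle_", side)
    zT <- jc[[paste0(hip, "_dist")]] - jc[[paste0(knee, "_prox")]]
    if (sqrt(sum(zT^2)) < 1e-6)
      stop("degenerate-axes error: thigh hip and knee centers coincide")
    frames[[paste0("thigh_", side)]] <-
      pcsFromAxes(ax[[paste0(knee, "_prox")]], zT)
    zS <- jc[[paste0(knee, "_dist")]] - jc[[paste0(ankle, "_prox")]]
    if (sqrt(sum(zS^2)) < 1e-6)
      stop("degenerate-axes error: shank knee and ankle centers coincide")
    frames[[paste0("shank_", side)]] <-
      pcsFromAxes(ax[[paste0(knee, "_dist")]], zS)
    zF <- jc[[paste0(ankle, "_dist")]]
    frames[[paste0("foot_", side)]] <-
      pcsFromAxes(ax[[paste0(ankle, "_dist")]], zF)
  }
  frames
}

#' Cardan decomposition with fixed e1 (proximal x) and e3 (distal z)
#'
#' Decomposes a joint rotation `R = Rx(fe) Ry(aa') Rz(ie')` (proximal-to-
#' distal anatomical rotation) into flexion about the proximal medio-lateral
#' axis, ab/adduction about the floating axis and axial rotation about the
#' distal longitudinal axis. For the left side the last two angles are
#' negated so positive means adduction/internal rotation on both sides.
#'
#' @param R 3 x 3 joint rotation (distal anatomical coordinates into
#'   proximal anatomical coordinates).
#' @param side "right" or "left".
#' @return named vector (fe, aa, ie), degrees.
#' @export
cardanE1FloatingE3 <- function(R, side = "right") {
  s13 <- max(-1, min(1, R[1, 3]))
  if (abs(asin(s13)) * 180 / pi >= 90 - 1e-6)
    stop("singularity error: ab/adduction within 1e-6 deg of 90")
  fe <- atan2(-R[2, 3], R[3, 3])
  aa <- asin(s13)
  ie <- atan2(-R[1, 2], R[1, 1])
  m <- if (side == "left") -1 else 1
  c(fe = fe, aa = m * aa, ie = m * ie) * 180 / pi
}

# vectorized decomposition straight from batch joint quaternions
cardanFromQuat <- function(qj, side) {
  w <- qj[, 1]; x <- qj[, 2]; y <- qj[, 3]; z <- qj[, 4]
  r13 <- 2 * (x * z + w * y)
  r23 <- 2 * (y * z - w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  r12 <- 2 * (x * y - w * z)
  r11 <- 1 - 2 * (y^2 + z^2)
  s13 <- pmax(-1, pmin(1, r13))
  if (any(abs(asin(s13)) * 180 / pi >= 90 - 1e-6))
    stop("singularity error: ab/adduction within 1e-6 deg of 90")
  m <- if (side == "left") -1 else 1
  cbind(fe = atan2(-r23, r33),
        aa = m * asin(s13),
        ie = m * atan2(-r12, r11)) * 180 / pi
}

# joint angle series from two sensor trajectories and their anatomical
# frames (B matrices, sensor -> anatomical)
jointAngleFromStates <- function(prox, dist, Bprox, Bdist, joint, side,
                                 convention) {
  qBp <- matrixToQuat(Bprox)                # anat axes in sensor frame
  qBd <- quatConj(matrixToQuat(Bdist))
  # R_joint = Bp R_proxSensor^T R_distSensor Bd^T
  qj <- quatMult(quatMult(matrix(qBp, 1)[rep(1, nrow(prox@q)), ],
                          quatMult(quatConj(prox@q), dist@q)),
                 matrix(qBd, 1)[rep(1, nrow(prox@q)), ])
  ang <- cardanFromQuat(quatNormalize(qj), side)
  JointAngleSeries(prox@times, ang[, "fe"], ang[, "aa"], ang[, "ie"],
                   joint = joint, side = side, convention = convention)
}

#' Hip angle series from an estimated solution
#'
#' Composes the world pelvis frame (lumbar state x pelvic anatomical frame)
#' with each femur frame (thigh state x thigh anatomical frame) and
#' decomposes with [cardanE1FloatingE3()] semantics.
#'
#' @param solution a [Solution-class].
#' @param v optional pelvic vertical; computed from the lumbar trajectory
#'   over the whole window when omitted.
#' @return named list with JointAngleSeries `hip_r` and `hip_l`.
#' @export
hipAngles <- function(solution, v = NULL) {
  lum <- solution@trajectories[["lumbar"]]
  if (is.null(v)) v <- pelvicVertical(lum)
  Bp <- pelvisOrientation(solution@calibration, v)
  sf <- segmentFrames(solution@calibration)
  out <- list()
  for (side in c("r", "l")) {
    sideName <- if (side == "r") "right" else "left"
    out[[paste0("hip_", side)]] <- jointAngleFromStates(
      lum, solution@trajectories[[paste0("thigh_", side)]],
      Bp, sf[[paste0("thigh_", side)]], "hip", sideName, "wu_modified")
  }
  out
}

#' Knee angle series from an estimated solution
#'
#' @param solution a [Solution-class].
#' @return named list with JointAngleSeries `knee_r` and `knee_l`.
#' @export
kneeAngles <- function(solution) {
  sf <- segmentFrames(solution@calibration)
  out <- list()
  for (side in c("r", "l")) {
    sideName <- if (side == "r") "right" else "left"
    out[[paste0("knee_", side)]] <- jointAngleFromStates(
      solution@trajectories[[paste0("thigh_", side)]],
      solution@trajectories[[paste0("shank_", side)]],
      sf[[paste0("thigh_", side)]], sf[[paste0("shank_", side)]],
      "knee", sideName, "grood_suntay")
  }
  out
}
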