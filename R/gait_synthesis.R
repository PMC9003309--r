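# Synthetic lower-body motion and rigid-mount IMU simulation.
#
# The generator produces ground-truth joint kinematics (periodic walking or a
# 3-DOF-exciting calibration motion), runs them through a rigid-body forward
# kinematic chain, and simulates rigidly mounted IMUs by differencing the
# resulting pose sequences. Gyro samples are defined as the exact body-frame
# orientation increment per time step, and accelerometer samples as the exact
# forward-difference specific force, so that first-order strapdown
# integration of the noiseless signals reproduces the true trajectories to
# machine precision. This makes noiseless closed-loop tests sharp: any
# residual error is attributable to the estimator, not the fixture.

#' SkeletonModel: lower-body segment dimensions
#'
#' @param pelvisWidth inter-hip-center distance, m.
#' @param thighLength,shankLength segment lengths, m.
#' @param footLength anterior ankle-to-toe distance, m (cosmetic).
#' @param ankleHeight standing ankle height, m.
#' @return list of positive lengths; left/right symmetric.
#' @export
skeletonModel <- function(pelvisWidth = 0.24, thighLength = 0.42,
                          shankLength = 0.41, footLength = 0.20,
                          ankleHeight = 0.08) {
  sk <- list(pelvisWidth = pelvisWidth, thighLength = thighLength,
             shankLength = shankLength, footLength = footLength,
             ankleHeight = ankleHeight)
  if (any(unlist(sk) <= 0)) stop("argument error: segment lengths must be > 0")
  sk
}

#' MountSpec: rigid sensor mounting (orientation offset + lever arm)
#'
#' Sensors are strapped roughly aligned with their segment but with an
#' unknown moderate orientation offset and lever arm; both are drawn once per
#' trial from a seeded RNG. Orientation offsets are uniform random axes with
#' angles up to `maxAngleDeg`; lever arms jitter around plausible strap
#' locations.
#'
#' @param seed integer seed.
#' @param maxAngleDeg largest mount misalignment angle, deg.
#' @return named list per sensor: `q` (unit quaternion, sensor -> segment)
#'   and `lever` (sensor origin in segment frame, m).
#' @export
mountSpec <- function(seed = 1, maxAngleDeg = 25) {
  nominal <- list(
    lumbar  = c(0.00, -0.12, 0.08),
    thigh_r = c(0.08,  0.03, -0.22), thigh_l = c(-0.08, 0.03, -0.22),
    shank_r = c(0.05,  0.04, -0.18), shank_l = c(-0.05, 0.04, -0.18),
    foot_r  = c(0.00,  0.08,  0.02), foot_l  = c(0.00, 0.08, 0.02))
  withSeed(seed * 7919L + 13L, {
    out <- lapply(imuPlacements(), function(id) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- stats::runif(1, 0.1, maxAngleDeg) * pi / 180
      lever <- nominal[[id]] + stats::runif(3, -0.02, 0.02)
      list(q = quatExp(ax * ang), lever = lever)
    })
    names(out) <- imuPlacements()
    out
  })
}

# evaluate an expression with a temporary RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' NoiseSpec: sensor noise and constant biases
#'
#' Defaults emulate a consumer-grade MEMS IMU at 200 Hz.
#'
#' @param sigmaGyro gyro white-noise RMS per sample, rad/s.
#' @param sigmaAccel accelerometer white-noise RMS per sample, m/s^2.
#' @param biasGyro,biasAccel half-width of the uniform distribution the
#'   constant per-axis biases are drawn from (rad/s, m/s^2).
#' @param seed RNG seed for noise and bias draws.
#' @export
noiseSpec <- function(sigmaGyro = 0.01, sigmaAccel = 0.1,
                      biasGyro = 0.01, biasAccel = 0.05, seed = 1) {
  v <- list(sigmaGyro = sigmaGyro, sigmaAccel = sigmaAccel,
            biasGyro = biasGyro, biasAccel = biasAccel, seed = seed)
  if (any(unlist(v[1:4]) < 0)) stop("argument error: negative noise magnitude")
  v
}

#' Noise-free NoiseSpec
#' @export
noiselessSpec <- function() noiseSpec(0, 0, 0, 0, seed = 1)

# ---------------------------------------------------------------------------
# JointAngleProfiles

#' JointAngleProfiles: ground-truth joint angle channels
#'
#' @slot t times, s. @slot fs sampling rate, Hz.
#' @slot channels named list (one per joint in [jointNames()]) of N x 3
#'   matrices with columns fe, aa, ie in degrees, reported convention
#'   (positive flexion/adduction/internal on both sides).
#' @slot eventsR,eventsL knee-maximum-flexion times per leg, s.
#' @slot meta generator settings.
#' @export
setClass("JointAngleProfiles",
  representation(t = "numeric", fs = "numeric", channels = "list",
                 eventsR = "numeric", eventsL = "numeric", meta = "list"))

setValidity("JointAngleProfiles", function(object) {
  n <- length(object@t)
  for (ch in object@channels)
    if (nrow(ch) != n || !all(is.finite(ch)))
      return("channels must be finite with one row per sample")
  TRUE
})

setMethod("show", "JointAngleProfiles", function(object) {
  cat(sprintf("JointAngleProfiles: %d samples @ %g Hz, %d joints, %d cycles\n",
              length(object@t), object@fs, length(object@channels),
              max(0L, length(object@eventsR) - 1L)))
})

# knee flexion waveform over one stride, phase in radians (phase 0 ~ maximum
# flexion / toe off). Three-harmonic Fourier series shaped to the canonical
# double-bump pattern: dominant swing peak and a smaller loading-response
# bump about one third of its height, minimum near full extension.
kneeWave <- function(phi, rom = 60) {
  raw <- function(p)
    16.7292 + 15.3038 * cos(p) + 2.8582 * sin(p) +
      13.6920 * cos(2 * p) + 10.7649 * sin(2 * p) +
      7.4955 * cos(3 * p) + 3.4153 * sin(3 * p)
  # normalize so min = 0, max = rom (constants fixed; scan one cycle once)
  pg <- seq(0, 2 * pi, length.out = 4001)
  rg <- raw(pg)
  (raw(phi) - min(rg)) / (max(rg) - min(rg)) * rom
}

# Quiet-standing lead-in. Recording protocols start with the subject
# standing still; besides realism this is what makes the constant sensor
# biases observable (the static span separates gyro bias from motion and
# anchors tilt). The motion starts through a C1 time warp: warped motion
# time tau(t) is 0 during the lead-in, accelerates quadratically over the
# blend, then advances at unit rate. Warping time (rather than scaling
# amplitudes) preserves the number and height of waveform peaks.
timeWarp <- function(t, leadIn, blend) {
  tau <- pmax(0, t - leadIn - blend / 2)
  inBlend <- t > leadIn & t <= leadIn + blend
  tau[inBlend] <- (t[inBlend] - leadIn)^2 / (2 * blend)
  tau
}

# inverse warp: motion time -> recording time
timeUnwarp <- function(tau, leadIn, blend) {
  ifelse(tau <= blend / 2, leadIn + sqrt(pmax(0, 2 * blend * tau)),
         tau + leadIn + blend / 2)
}

#' Periodic walking joint-angle profiles
#'
#' Antiphase left/right truncated-Fourier profiles: hip flexion/extension is
#' dominant; hip ab/adduction and internal/external rotation are small (and
#' identically zero when `degenerate1dof`, emulating a strictly 1-DOF hip
#' gait); the knee uses a two-peak flexion waveform per cycle. The recording
#' begins with `leadIn` seconds of quiet standing and blends into gait
#' through a smooth time warp, as in a typical capture protocol.
#'
#' @param duration gait duration, s (excluding the lead-in).
#' @param fs Hz. @param cadence steps/min (2 steps per
#'   gait cycle). @param amplitudes list of channel amplitudes in degrees:
#'   hipFe, hipAa, hipIe, kneeRom, ankleFe.
#' @param degenerate1dof if TRUE, zero the hip ab/ad and int/ext channels
#'   (and the pelvic orientation sway, keeping the pelvis orientation
#'   static).
#' @param leadIn quiet-standing duration, s. @param blend warp-in time, s.
#' @return a [JointAngleProfiles-class].
#' @export
gaitProfile <- function(duration, fs, cadence = 100,
                        amplitudes = list(), degenerate1dof = FALSE,
                        leadIn = 2, blend = 1) {
  if (duration <= 0 || fs <= 0 || cadence <= 0)
    stop("argument error: duration, fs, cadence must be > 0")
  amp <- utils::modifyList(list(hipFe = 20, hipAa = 4, hipIe = 3.5,
                                kneeRom = 60, ankleFe = 8), amplitudes)
  if (any(unlist(amp) < 0)) stop("argument error: negative amplitude")
  t <- seq(0, duration + leadIn + blend / 2, by = 1 / fs)
  tau <- timeWarp(t, leadIn, blend)
  fc <- cadence / 120              # gait cycles (strides) per second per leg
  # start the cycle near full knee extension so the standing posture is
  # natural; located once from the waveform
  pg <- seq(0, 2 * pi, length.out = 20001)
  phi0 <- pg[which.min(kneeWave(pg))]
  phiR <- phi0 + 2 * pi * fc * tau
  phiL <- phiR + pi                # antiphase
  hip <- function(phi) cbind(
    fe = amp$hipFe * cos(phi) - 0.2 * amp$hipFe * cos(2 * phi),
    aa = if (degenerate1dof) 0 * phi else amp$hipAa * sin(phi),
    ie = if (degenerate1dof) 0 * phi else amp$hipIe * sin(phi + 0.6))
  knee <- function(phi) cbind(fe = kneeWave(phi, amp$kneeRom),
                              aa = 0 * phi, ie = 0 * phi)
  ankle <- function(phi) cbind(fe = amp$ankleFe * sin(phi + 1.1),
                               aa = 0 * phi, ie = 0 * phi)
  channels <- list(hip_r = hip(phiR), hip_l = hip(phiL),
                   knee_r = knee(phiR), knee_l = knee(phiL),
                   ankle_r = ankle(phiR), ankle_l = ankle(phiL))
  # knee maximum flexion: fixed phase of the waveform; locate it once
  phiMax <- pg[which.max(kneeWave(pg))]
  evR <- timeUnwarp(eventTimes(phiMax - phi0, fc, max(tau)), leadIn, blend)
  evL <- timeUnwarp(eventTimes(phiMax - phi0 - pi, fc, max(tau)), leadIn,
                    blend)
  new("JointAngleProfiles", t = t, fs = fs, channels = channels,
      eventsR = evR, eventsL = evL,
      meta = list(kind = "walking", cadence = cadence, amplitudes = amp,
                  degenerate1dof = degenerate1dof, tau = tau,
                  leadIn = leadIn, blend = blend))
}

# motion times in [0, duration] at which phase offset = phi0 (mod 2*pi)
eventTimes <- function(phi0, fc, duration) {
  period <- 1 / fc
  t0 <- (phi0 / (2 * pi)) %% 1 * period
  ev <- seq(t0, duration, by = period)
  ev[ev >= 0 & ev <= duration]
}

#' Calibration-motion joint-angle profiles
#'
#' A smooth motion that excites all three hip degrees of freedom on both
#' sides (each hip channel sweeps a peak-to-peak range of at least 30 deg)
#' and flexes the knees through at least 60 deg, so that the full
#' calibration problem (all joint-center vectors and hinge axes) is
#' identifiable without priors. The pelvis is held static.
#'
#' @param duration motion duration, s, >= 10 (excluding the lead-in).
#' @param fs Hz.
#' @param leadIn quiet-standing duration, s. @param blend warp-in time, s.
#' @return a [JointAngleProfiles-class].
#' @export
calibrationProfile <- function(duration = 60, fs = 200, leadIn = 2,
                               blend = 1) {
  if (duration < 10) stop("argument error: calibration needs >= 10 s")
  tRec <- seq(0, duration + leadIn + blend / 2, by = 1 / fs)
  tau <- timeWarp(tRec, leadIn, blend)
  # deep hip excursions (leg raised well away from vertical) are what make
  # the sensor-to-hip-center vectors and the lumbar-thigh heading relation
  # well conditioned; shallow swings leave the thigh long axis near
  # vertical and the problem ill-conditioned. Left/right use slightly
  # different frequencies (all channels vanish at the standing posture).
  hip <- function(f1, f2, f3) cbind(
    fe = 30 * (1 - cos(2 * pi * f1 * tau)),
    aa = 25 * sin(2 * pi * f2 * tau),
    ie = 17 * sin(2 * pi * f3 * tau))
  knee <- function(f) cbind(fe = 40 * (1 - cos(2 * pi * f * tau)),
                            aa = 0 * tau, ie = 0 * tau)
  ankle <- function(f) cbind(fe = 12 * sin(2 * pi * f * tau),
                             aa = 0 * tau, ie = 0 * tau)
  channels <- list(hip_r = hip(0.20, 0.27, 0.34),
                   hip_l = hip(0.23, 0.29, 0.37),
                   knee_r = knee(0.15), knee_l = knee(0.17),
                   ankle_r = ankle(0.25), ankle_l = ankle(0.28))
  new("JointAngleProfiles", t = tRec, fs = fs, channels = channels,
      eventsR = numeric(), eventsL = numeric(),
      meta = list(kind = "calibration", tau = tau, leadIn = leadIn,
                  blend = blend))
}

#' Pelvis motion specification for walking
#'
#' Small vertical/lateral translation sinusoids plus small roll/pitch sway,
#' zero mean heading (bounded displacement, as on a treadmill).
#' @param vert,lat translation amplitudes, m. @param rollDeg,pitchDeg
#'   orientation sway amplitudes, deg (zeroed for degenerate 1-DOF gait).
#' @export
pelvisMotionSpec <- function(vert = 0.02, lat = 0.025, rollDeg = 2,
                             pitchDeg = 1.5) {
  list(vert = vert, lat = lat, rollDeg = rollDeg, pitchDeg = pitchDeg)
}

# joint rotation matrix from reported-convention angles (deg); left side
# mirrors ab/ad and int/ext so that positive = adduction/internal bilaterally
jointRotation <- function(feDeg, aaDeg, ieDeg, side) {
  s <- if (side == "left") -1 else 1
  d2r <- pi / 180
  rotX(feDeg * d2r) %*% rotY(s * aaDeg * d2r) %*% rotZ(s * ieDeg * d2r)
}

#' Forward kinematics of the lower-body chain
#'
#' Computes world-frame pose trajectories (orientation quaternion + origin
#' position) for pelvis, thighs, shanks and feet. Segment frames: x right,
#' y anterior, z proximal; thigh/shank/foot origins sit at their proximal
#' joint center, so adjacent segments share joint points exactly.
#'
#' @param profiles a [JointAngleProfiles-class].
#' @param skeleton from [skeletonModel()].
#' @param pelvisMotion from [pelvisMotionSpec()], or NULL for a static
#'   pelvis.
#' @return named list of segments, each `list(q = N x 4, p = N x 3)`.
#' @export
forwardKinematics <- function(profiles, skeleton = skeletonModel(),
                              pelvisMotion = NULL) {
  t <- profiles@t
  n <- length(t)
  tau <- profiles@meta$tau
  if (is.null(tau)) tau <- t
  degen <- isTRUE(profiles@meta$degenerate1dof)
  h0 <- skeleton$thighLength + skeleton$shankLength + skeleton$ankleHeight
  if (identical(profiles@meta$kind, "calibration")) {
    # the calibration task sways the whole trunk: without pelvic rotation
    # the lumbar sensor is static and the lumbar-to-hip-center vectors are
    # structurally confounded with the (gauge-fixed) lumbar pose
    roll <- 20 * pi / 180 * sin(2 * pi * 0.11 * tau)
    pitch <- 16 * pi / 180 * sin(2 * pi * 0.17 * tau)
    yaw <- 25 * pi / 180 * sin(2 * pi * 0.13 * tau)
    qPelvis <- quatMult(quatExp(cbind(0, 0, yaw)),
                        quatMult(quatExp(cbind(roll, 0, 0)),
                                 quatExp(cbind(0, pitch, 0))))
    pPelvis <- cbind(0.08 * sin(2 * pi * 0.19 * tau),
                     0.10 * sin(2 * pi * 0.12 * tau),
                     h0 + 0.06 * sin(2 * pi * 0.23 * tau))
  } else if (is.null(pelvisMotion)) {
    pPelvis <- cbind(0 * t, 0 * t, h0 + 0 * t)
    qPelvis <- matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
  } else {
    fc <- profiles@meta$cadence / 120
    w1 <- 2 * pi * fc
    pPelvis <- cbind(0.0 * tau,
                     pelvisMotion$lat * sin(w1 * tau),
                     h0 + pelvisMotion$vert * sin(2 * w1 * tau))
    roll <- if (degen) 0 * tau else
      pelvisMotion$rollDeg * pi / 180 * sin(w1 * tau)
    pitch <- if (degen) 0 * tau else
      pelvisMotion$pitchDeg * pi / 180 * sin(2 * w1 * tau)
    qPelvis <- quatMult(quatExp(cbind(roll, 0, 0)),
                        quatExp(cbind(0, pitch, 0)))
  }
  segs <- list(pelvis = list(q = quatNormalize(qPelvis), p = pPelvis))
  for (side in c("r", "l")) {
    sgn <- if (side == "r") 1 else -1
    sideName <- if (side == "r") "right" else "left"
    hipCh <- profiles@channels[[paste0("hip_", side)]]
    kneeCh <- profiles@channels[[paste0("knee_", side)]]
    ankleCh <- profiles@channels[[paste0("ankle_", side)]]
    qHipJ <- t(vapply(seq_len(n), function(k)
      matrixToQuat(jointRotation(hipCh[k, 1], hipCh[k, 2], hipCh[k, 3],
                                 sideName)), numeric(4)))
    qKneeJ <- t(vapply(seq_len(n), function(k)
      matrixToQuat(jointRotation(kneeCh[k, 1], kneeCh[k, 2], kneeCh[k, 3],
                                 sideName)), numeric(4)))
    qAnkleJ <- t(vapply(seq_len(n), function(k)
      matrixToQuat(jointRotation(ankleCh[k, 1], ankleCh[k, 2], ankleCh[k, 3],
                                 sideName)), numeric(4)))
    pHip <- segs$pelvis$p +
      quatRotate(segs$pelvis$q, c(sgn * skeleton$pelvisWidth / 2, 0, 0))
    qThigh <- quatNormalize(quatMult(segs$pelvis$q, qHipJ))
    pKnee <- pHip + quatRotate(qThigh, c(0, 0, -skeleton$thighLength))
    qShank <- quatNormalize(quatMult(qThigh, qKneeJ))
    pAnkle <- pKnee + quatRotate(qShank, c(0, 0, -skeleton$shankLength))
    qFoot <- quatNormalize(quatMult(qShank, qAnkleJ))
    segs[[paste0("thigh_", side)]] <- list(q = qThigh, p = pHip)
    segs[[paste0("shank_", side)]] <- list(q = qShank, p = pKnee)
    segs[[paste0("foot_", side)]] <- list(q = qFoot, p = pAnkle)
  }
  segs
}

#' Simulate IMU recordings from segment poses
#'
#' Inverse sensor model: each sensor pose is the rigid composition of its
#' segment pose with its mount; the gyro sample at step k is the exact
#' body-frame orientation increment over [k, k+1) divided by dt, and the
#' accelerometer sample is the forward-difference specific force
#' (world acceleration minus gravity, rotated into the sensor frame).
#' Constant biases and white noise are then added from a seeded RNG.
#'
#' @param segmentPoses from [forwardKinematics()].
#' @param mounts from [mountSpec()].
#' @param noise from [noiseSpec()].
#' @param fs sampling rate, Hz (must match the pose sampling).
#' @param t sample times, s.
#' @return list with `array` ([SensorArray-class]) and `states` (named list
#'   of true [StateTrajectory-class] per sensor).
#' @export
synthesizeImu <- function(segmentPoses, mounts, noise, fs, t) {
  n <- length(t)
  dt <- 1 / fs
  if (abs((t[2] - t[1]) - dt) > 1e-9)
    stop("argument error: fs does not match pose sampling")
  gW <- c(0, 0, -9.81)
  recs <- list()
  states <- list()
  draws <- withSeed(noise$seed * 104729L + 7L, {
    lapply(imuPlacements(), function(id) list(
      bg = stats::runif(3, -noise$biasGyro, noise$biasGyro),
      ba = stats::runif(3, -noise$biasAccel, noise$biasAccel),
      wg = matrix(stats::rnorm(3 * n, 0, noise$sigmaGyro), ncol = 3),
      wa = matrix(stats::rnorm(3 * n, 0, noise$sigmaAccel), ncol = 3)))
  })
  names(draws) <- imuPlacements()
  segOf <- c(lumbar = "pelvis", thigh_r = "thigh_r", thigh_l = "thigh_l",
             shank_r = "shank_r", shank_l = "shank_l",
             foot_r = "foot_r", foot_l = "foot_l")
  for (id in imuPlacements()) {
    seg <- segmentPoses[[segOf[[id]]]]
    m <- mounts[[id]]
    q <- quatNormalize(quatMult(seg$q, m$q))
    p <- seg$p + quatRotate(seg$q, m$lever)
    # body-frame orientation increments
    dq <- quatMult(quatConj(q[-n, , drop = FALSE]), q[-1, , drop = FALSE])
    w <- quatLog(dq) / dt
    w <- rbind(w, w[n - 1, ])
    v <- (p[-1, , drop = FALSE] - p[-n, , drop = FALSE]) / dt
    v <- rbind(v, v[n - 1, ])
    aw <- (v[-1, , drop = FALSE] - v[-n, , drop = FALSE]) / dt
    aw <- rbind(aw, aw[n - 1, ])
    f <- quatRotate(quatConj(q), sweep(aw, 2, gW))
    d <- draws[[id]]
    recs[[id]] <- ImuRecording(id, t,
      gyro = w + matrix(d$bg, n, 3, byrow = TRUE) + d$wg,
      accel = f + matrix(d$ba, n, 3, byrow = TRUE) + d$wa, fs = fs)
    states[[id]] <- StateTrajectory(id, t, q = q, p = p, v = v,
                                    bg = d$bg, ba = d$ba)
  }
  list(array = assembleArray(recs), states = states)
}

# true calibration implied by skeleton + mounts
truthCalibrationFrom <- function(skeleton, mounts) {
  jointInSeg <- function(joint, which) {
    w <- skeleton$pelvisWidth / 2
    s <- if (grepl("_r$", joint)) 1 else -1
    base <- sub("_[rl]$", "", joint)
    if (which == "prox") {
      switch(base,
        hip = c(s * w, 0, 0),                      # pelvis frame
        knee = c(0, 0, -skeleton$thighLength),     # thigh frame
        ankle = c(0, 0, -skeleton$shankLength))    # shank frame
    } else {
      c(0, 0, 0)                                   # distal segment origin
    }
  }
  sensorOf <- function(joint, which) {
    js <- jointSensors(joint)
    if (which == "prox") js[1] else js[2]
  }
  jc <- list(); ax <- list()
  for (joint in jointNames()) for (which in c("prox", "dist")) {
    id <- sensorOf(joint, which)
    m <- mounts[[id]]
    Rm <- quatToMatrix(m$q)                        # sensor -> segment
    cSeg <- jointInSeg(joint, which)
    jc[[paste0(joint, "_", which)]] <- as.numeric(t(Rm) %*% (cSeg - m$lever))
    ax[[paste0(joint, "_", which)]] <- as.numeric(t(Rm) %*% c(1, 0, 0))
  }
  CalibrationParameters(jc, ax)
}

#' Inject gait-phase-locked soft-tissue perturbations
#'
#' Regenerates the thigh and/or shank sensor signals of a walking trial from
#' mount orientations that rotate smoothly about the segment's flexion axis
#' as a function of gait phase: `stanceDeg` degrees in mid-stance, `swingDeg`
#' in mid-swing, returning to the nominal mount within `transitionWidth` of
#' the phase boundaries (C1-continuous raised-cosine windows). This emulates
#' the tension/compression cycle of skin and muscle under a strapped sensor.
#'
#' @param trial a walking [SyntheticTrial-class].
#' @param stanceDeg,swingDeg perturbation amplitudes, deg (|x| <= 30).
#' @param segments which sensors to perturb (default both shanks).
#' @param transitionWidth half-width of the phase transition, fraction of the
#'   cycle (default 0.10).
#' @param swingEnd phase fraction at which swing ends and stance begins; the
#'   cycle starts at knee maximum flexion (approximately toe off), so swing
#'   occupies the first part of the cycle.
#' @return a new [SyntheticTrial-class] with perturbed recordings; the truth
#'   slots are unchanged (the perturbation is an artifact, not motion).
#' @export
injectSoftTissue <- function(trial, stanceDeg, swingDeg,
                             segments = c("shank_r", "shank_l"),
                             transitionWidth = 0.10, swingEnd = 0.40) {
  if (max(abs(c(stanceDeg, swingDeg))) > 30)
    stop("argument error: perturbation > 30 deg is nonphysical")
  if (stanceDeg == 0 && swingDeg == 0) return(trial)
  meta <- trial@meta
  if (is.null(meta$profiles)) stop("trial does not carry generator settings")
  poses <- forwardKinematics(meta$profiles, meta$skeleton, meta$pelvisMotion)
  mounts <- meta$mounts
  t <- meta$profiles@t
  for (id in segments) {
    side <- if (grepl("_r$", id)) "R" else "L"
    ev <- if (side == "R") meta$profiles@eventsR else meta$profiles@eventsL
    ph <- phaseFromEvents(t, ev)
    delta <- softTissueWave(ph, stanceDeg, swingDeg, transitionWidth,
                            swingEnd) * pi / 180
    # rotate the sensor about the segment flexion axis (segment x)
    qPert <- quatExp(cbind(delta, 0, 0))
    m0 <- meta$mounts[[id]]
    mounts[[id]]$qSeries <-
      quatMult(qPert, matrix(m0$q, nrow = 1)[rep(1, length(t)), ])
  }
  sim <- synthesizeImuTimeVarying(poses, mounts, meta$noise, meta$profiles@fs, t)
  initialize(trial, array = sim$array,
             meta = utils::modifyList(meta, list(
               softTissue = list(stanceDeg = stanceDeg, swingDeg = swingDeg,
                                 segments = segments,
                                 transitionWidth = transitionWidth,
                                 swingEnd = swingEnd))))
}

# phase in [0, 1) from event times, linear interpolation between events;
# samples before the first / after the last event extrapolate the
# neighbouring cycle period
phaseFromEvents <- function(t, ev) {
  if (length(ev) < 2) stop("segmentation error: need >= 2 events for phase")
  idx <- findInterval(t, ev)
  period <- diff(ev)
  lo <- pmin(pmax(idx, 1L), length(ev) - 1L)
  ph <- (t - ev[lo]) / period[lo]
  ph %% 1
}

# C1 phase-locked perturbation profile, deg. Swing occupies [0, swingEnd),
# stance [swingEnd, 1); each plateau is windowed by a raised-cosine bump that
# is zero within +/- tw of the boundaries.
softTissueWave <- function(ph, stanceDeg, swingDeg, tw, swingEnd) {
  bump <- function(x, a, b) {
    # 0 at a and b, 1 on [a+tw, b-tw], cosine ramps between
    y <- numeric(length(x))
    inside <- x >= a & x <= b
    xi <- x[inside]
    up <- pmin(1, pmax(0, (xi - a) / tw))
    down <- pmin(1, pmax(0, (b - xi) / tw))
    y[inside] <- ((1 - cos(pi * up)) / 2) * ((1 - cos(pi * down)) / 2)
    y
  }
  swingDeg * bump(ph, 0, swingEnd) + stanceDeg * bump(ph, swingEnd, 1)
}

# variant of synthesizeImu that honours per-sample mount quaternions
synthesizeImuTimeVarying <- function(segmentPoses, mounts, noise, fs, t) {
  n <- length(t); dt <- 1 / fs
  gW <- c(0, 0, -9.81)
  draws <- withSeed(noise$seed * 104729L + 7L, {
    lapply(imuPlacements(), function(id) list(
      bg = stats::runif(3, -noise$biasGyro, noise$biasGyro),
      ba = stats::runif(3, -noise$biasAccel, noise$biasAccel),
      wg = matrix(stats::rnorm(3 * n, 0, noise$sigmaGyro), ncol = 3),
      wa = matrix(stats::rnorm(3 * n, 0, noise$sigmaAccel), ncol = 3)))
  })
  names(draws) <- imuPlacements()
  segOf <- c(lumbar = "pelvis", thigh_r = "thigh_r", thigh_l = "thigh_l",
             shank_r = "shank_r", shank_l = "shank_l",
             foot_r = "foot_r", foot_l = "foot_l")
  recs <- list()
  for (id in imuPlacements()) {
    seg <- segmentPoses[[segOf[[id]]]]
    m <- mounts[[id]]
    qm <- if (!is.null(m$qSeries)) m$qSeries else
      matrix(m$q, nrow = 1)[rep(1, n), , drop = FALSE]
    q <- quatNormalize(quatMult(seg$q, qm))
    p <- seg$p + quatRotate(seg$q, m$lever)
    dq <- quatMult(quatConj(q[-n, , drop = FALSE]), q[-1, , drop = FALSE])
    w <- rbind(quatLog(dq) / dt, matrix(0, 1, 3)); w[n, ] <- w[n - 1, ]
    v <- (p[-1, , drop = FALSE] - p[-n, , drop = FALSE]) / dt
    v <- rbind(v, v[n - 1, ])
    aw <- (v[-1, , drop = FALSE] - v[-n, , drop = FALSE]) / dt
    aw <- rbind(aw, aw[n - 1, ])
    f <- quatRotate(quatConj(q), sweep(aw, 2, gW))
    d <- draws[[id]]
    recs[[id]] <- ImuRecording(id, t,
      gyro = w + matrix(d$bg, n, 3, byrow = TRUE) + d$wg,
      accel = f + matrix(d$ba, n, 3, byrow = TRUE) + d$wa, fs = fs)
  }
  list(array = assembleArray(recs))
}

#' Generate a complete synthetic trial
#'
#' Bundles profiles -> forward kinematics -> IMU synthesis and records the
#' implied ground truth (angles, per-sensor state trajectories, true
#' sensor-to-joint-center calibration).
#'
#' @param kind "walking" or "calibration".
#' @param seed integer; fixes profiles' mounts, biases and noise. The same
#'   seed yields a bit-identical trial.
#' @param duration s (default 30 walking / 60 calibration). @param fs Hz.
#' @param cadence steps/min (walking). @param degenerate1dof zero hip ab/ad
#'   and int/ext channels and pelvic sway (walking).
#' @param noise a [noiseSpec()]; its seed is overridden by `seed`.
#' @param amplitudes passed to [gaitProfile()].
#' @param skeleton,mounts,pelvisMotion optional overrides.
#' @return a [SyntheticTrial-class].
#' @export
generateTrial <- function(kind = c("walking", "calibration"), seed = 1,
                          duration = NULL, fs = 200, cadence = 100,
                          degenerate1dof = FALSE, noise = noiseSpec(),
                          amplitudes = list(), skeleton = skeletonModel(),
                          mounts = NULL, pelvisMotion = pelvisMotionSpec()) {
  kind <- match.arg(kind)
  if (is.null(duration)) duration <- if (kind == "walking") 30 else 60
  noise$seed <- seed
  if (is.null(mounts)) mounts <- mountSpec(seed)
  profiles <- if (kind == "walking")
    gaitProfile(duration, fs, cadence, amplitudes, degenerate1dof)
  else calibrationProfile(duration, fs)
  poses <- forwardKinematics(profiles, skeleton,
                             if (kind == "walking") pelvisMotion else NULL)
  sim <- synthesizeImu(poses, mounts, noise, fs, profiles@t)
  calib <- truthCalibrationFrom(skeleton, mounts)
  angles <- profilesToSeries(profiles)
  new("SyntheticTrial", array = sim$array, truthAngles = angles,
      truthCalibration = calib, truthStates = sim$states,
      events = profiles@eventsR, seed = seed,
      meta = list(kind = kind, profiles = profiles, skeleton = skeleton,
                  mounts = mounts, noise = noise,
                  pelvisMotion = if (kind == "walking") pelvisMotion else NULL,
                  eventsL = profiles@eventsL))
}

# convert profile channels to JointAngleSeries objects
profilesToSeries <- function(profiles) {
  out <- list()
  for (joint in jointNames()) {
    ch <- profiles@channels[[joint]]
    base <- sub("_[rl]$", "", joint)
    side <- if (grepl("_r$", joint)) "right" else "left"
    out[[joint]] <- JointAngleSeries(profiles@t, ch[, 1], ch[, 2], ch[, 3],
      joint = base, side = side,
      convention = if (base == "hip") "wu_modified" else "grood_suntay")
  }
  out
}
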