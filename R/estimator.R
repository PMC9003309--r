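# Windowed joint estimation of per-sensor pose trajectories and static
# sensor-to-joint calibration.
#
# The unknown vector stacks, per sensor, one (orientation, velocity,
# position) state per keyframe plus constant gyro/accel biases, followed by
# the twelve joint-center vectors and twelve hinge axes. Residuals:
#   * inertial: strapdown propagation of the raw measurements between
#     consecutive keyframes must reproduce the keyframe states;
#   * joint center: both sensors flanking a joint must place the shared
#     joint center at the same world point;
#   * hinge: both sensors must agree on the world direction of the joint's
#     hinge axis - tight for the knee (a good hinge), loose for the hip and
#     ankle ("noisy hinges" that pin relative heading without forbidding
#     non-hinge motion);
#   * axis unit-norm, Gaussian priors on the four hip-connected vectors
#     (walking), a gauge prior on the lumbar first keyframe
#     (position/velocity/heading), and weak zero-mean bias priors.
# The stacked whitened problem is solved with Levenberg-Marquardt on the
# manifold (rotations updated by right-multiplied exponential steps) using
# a sparse normal-equation Cholesky factorization.

#' Residual noise configuration
#'
#' @param sigmaGyro,sigmaAccel measurement white-noise RMS (rad/s, m/s^2).
#' @param sigmaJc joint-center residual scale, m (soft-tissue slop).
#' @param sigmaHingeKnee,sigmaHingeHip,sigmaHingeAnkle hinge axis-alignment
#'   residual scales, rad; the knee must be tighter than hip and ankle.
#' @param sigmaBiasGyro,sigmaBiasAccel zero-mean bias prior scales.
#' @param gravity m/s^2.
#' @export
noiseConfig <- function(sigmaGyro = 0.01, sigmaAccel = 0.1, sigmaJc = 0.01,
                        sigmaHingeKnee = 0.05, sigmaHingeHip = 0.3,
                        sigmaHingeAnkle = 0.3, sigmaBiasGyro = 0.02,
                        sigmaBiasAccel = 0.2, gravity = 9.81) {
  cfg <- list(sigmaGyro = sigmaGyro, sigmaAccel = sigmaAccel,
              sigmaJc = sigmaJc, sigmaHingeKnee = sigmaHingeKnee,
              sigmaHingeHip = sigmaHingeHip,
              sigmaHingeAnkle = sigmaHingeAnkle,
              sigmaBiasGyro = sigmaBiasGyro,
              sigmaBiasAccel = sigmaBiasAccel, gravity = gravity)
  if (any(unlist(cfg) <= 0) && !identical(cfg$sigmaGyro, 0) &&
      !identical(cfg$sigmaAccel, 0))
    stop("argument error: noise scales must be > 0")
  if (sigmaHingeKnee >= sigmaHingeHip || sigmaHingeKnee >= sigmaHingeAnkle)
    stop("argument error: knee hinge must be tighter than hip/ankle")
  cfg
}

#' Gaussian priors on the four hip-connected joint-center vectors
#'
#' @param means named list (names from [hipConnectedNames()]) of 3-vectors.
#' @param covs named list of 3 x 3 covariance matrices (positive definite).
#' @export
priorSpec <- function(means, covs) {
  nm <- hipConnectedNames()
  stopifnot(all(nm %in% names(means)), all(nm %in% names(covs)))
  for (n in nm) {
    ev <- eigen(covs[[n]], symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("argument error: prior covariance not positive definite")
  }
  structure(list(means = means[nm], covs = covs[nm]), class = "walkimuPriors")
}

#' Build walking priors from an estimated (or true) calibration
#'
#' Covariances are taken from the calibration when available and inflated by
#' `inflate` to hedge against calibration-vs-walking soft-tissue differences;
#' otherwise an isotropic `fallbackSd` is used.
#'
#' @param calib a [CalibrationParameters-class].
#' @param inflate variance inflation factor.
#' @param fallbackSd isotropic prior standard deviation, m.
#' @export
priorsFromCalibration <- function(calib, inflate = 4, fallbackSd = 0.01) {
  nm <- hipConnectedNames()
  means <- calib@jointCenters[nm]
  covs <- lapply(nm, function(n) {
    C <- calib@covariances[[n]]
    if (is.null(C)) diag(fallbackSd^2, 3) else C * inflate
  })
  names(covs) <- nm
  priorSpec(means, covs)
}

# ---------------------------------------------------------------------------
# Reference residuals (plain R). These mirror the compiled kernels and act
# as their independent cross-check in tests; the compiled path is the one
# the solver uses.

#' Strapdown inertial residual between two keyframe states
#'
#' Zero iff propagating `stateK` through the bias-corrected measurements
#' with gravity reproduces `stateK1`. Whitened by the measurement scales in
#' `cfg` accumulated over the interval.
#'
#' @param stateK,stateK1 lists with `q` (unit quaternion sensor->world),
#'   `v`, `p` (world m/s, m).
#' @param gyroSeg,accelSeg m x 3 raw measurements covering the interval.
#' @param dt raw sample period, s.
#' @param bg,ba constant biases.
#' @param cfg a [noiseConfig()].
#' @return whitened 9-vector (rotation, velocity, position blocks).
#' @export
residualInertial <- function(stateK, stateK1, gyroSeg, accelSeg, dt,
                             bg = c(0, 0, 0), ba = c(0, 0, 0),
                             cfg = noiseConfig()) {
  m <- nrow(gyroSeg)
  dq <- c(1, 0, 0, 0); dv <- c(0, 0, 0); dp <- c(0, 0, 0)
  for (j in seq_len(m)) {
    dp <- dp + dv * dt
    dv <- dv + quatRotate(dq, accelSeg[j, ] - ba) * dt
    dq <- quatMult(dq, quatExp((gyroSeg[j, ] - bg) * dt))
  }
  g <- c(0, 0, -cfg$gravity)
  Dt <- m * dt
  sR <- max(cfg$sigmaGyro, 1e-4) * dt * sqrt(m)
  sv <- max(cfg$sigmaAccel, 1e-3) * dt * sqrt(m)
  sp <- max(cfg$sigmaAccel, 1e-3) * dt^2 * sqrt(max(sum((seq_len(m) - 1)^2), 1))
  qrel <- quatMult(quatConj(dq), quatMult(quatConj(stateK$q), stateK1$q))
  rR <- quatLog(qrel) / sR
  rv <- (quatRotate(quatConj(stateK$q), stateK1$v - stateK$v - g * Dt) - dv) / sv
  rp <- (quatRotate(quatConj(stateK$q),
                    stateK1$p - stateK$p - stateK$v * Dt -
                      g * dt^2 * m * (m - 1) / 2) - dp) / sp
  c(rR, rv, rp)
}

#' Joint-center coincidence residual, meters
#'
#' `r = (pA + R_A sA) - (pB + R_B sB)`: zero iff both sensors place the
#' shared joint center at the same world point.
#'
#' @param stateA,stateB lists with `q` (or `R`) and `p`.
#' @param sA,sB joint-center vectors in the respective sensor frames, m.
#' @export
residualJointCenter <- function(stateA, stateB, sA, sB) {
  rot <- function(st, v) {
    if (!is.null(st$R)) as.numeric(st$R %*% v) else quatRotate(st$q, v)
  }
  (stateA$p + rot(stateA, sA)) - (stateB$p + rot(stateB, sB))
}

#' Hinge axis-alignment residual
#'
#' `r = R_A aA - R_B aB`: zero iff both sensors agree on the world direction
#' of the hinge axis.
#'
#' @param stateA,stateB lists with `q` (or `R`).
#' @param aA,aB unit axes in the respective sensor frames.
#' @export
residualHinge <- function(stateA, stateB, aA, aB) {
  if (abs(sqrt(sum(aA^2)) - 1) > 1e-6 || abs(sqrt(sum(aB^2)) - 1) > 1e-6)
    stop("argument error: hinge axes must be unit vectors")
  rot <- function(st, v) {
    if (!is.null(st$R)) as.numeric(st$R %*% v) else quatRotate(st$q, v)
  }
  rot(stateA, aA) - rot(stateB, aB)
}

# ---------------------------------------------------------------------------

#' Initial state trajectories by leveling + gyro dead-reckoning
#'
#' The initial orientation of each sensor is the minimal (zero-heading)
#' rotation aligning its mean specific force over the first 0.5 s with the
#' world vertical; orientations are then dead-reckoned through the raw gyro
#' and subsampled at the keyframe rate. Positions, velocities and biases
#' start at zero.
#'
#' @param array a [SensorArray-class].
#' @param keyframeRate Hz; must divide the sampling rate.
#' @param window optional sample span `c(first, last)` (1-based, inclusive).
#' @return named list of [StateTrajectory-class].
#' @export
initializeStates <- function(array, keyframeRate = 20, window = NULL) {
  fs <- sampleRate(array)
  m <- fs / keyframeRate
  if (abs(m - round(m)) > 1e-9)
    stop("argument error: keyframeRate must divide the sampling rate")
  m <- as.integer(round(m))
  t <- timestamps(array)
  n <- length(t)
  if (is.null(window)) window <- c(1L, n)
  lo <- window[1]; hi <- window[2]
  nLevel <- as.integer(round(0.5 * fs))
  if (hi - lo + 1 < nLevel)
    stop("argument error: need at least 0.5 s of data for leveling")
  K <- (hi - lo) %/% m + 1
  kf <- lo + (seq_len(K) - 1L) * m
  dt <- 1 / fs
  out <- list()
  for (id in imuPlacements()) {
    rec <- recordings(array)[[id]]
    aBar <- colMeans(rec@accel[lo:(lo + nLevel - 1L), , drop = FALSE])
    q0 <- levelingQuat(aBar)
    qAll <- .wk_deadreckon(q0, rec@gyro[lo:hi, , drop = FALSE], dt)
    out[[id]] <- StateTrajectory(id, t[kf], q = qAll[kf - lo + 1L, , drop = FALSE],
                                 p = matrix(0, K, 3), v = matrix(0, K, 3))
  }
  out
}

# minimal rotation (no heading twist) taking the measured up direction
# (mean specific force) to the world vertical
levelingQuat <- function(aBar) {
  a <- unit3(aBar)
  z <- c(0, 0, 1)
  cr <- c(a[2] * z[3] - a[3] * z[2], a[3] * z[1] - a[1] * z[3],
          a[1] * z[2] - a[2] * z[1])
  s <- sqrt(sum(cr^2)); c0 <- sum(a * z)
  if (s < 1e-12) {
    if (c0 > 0) return(c(1, 0, 0, 0))
    return(c(0, 1, 0, 0))  # upside down: 180 deg about x
  }
  quatExp(cr / s * atan2(s, c0))
}

#' Assemble the windowed estimation problem
#'
#' Collects the cropped measurements, residual bookkeeping, whitening
#' scales, priors and the gauge into a self-contained problem object, and
#' reports unknown/residual counts.
#'
#' @param array a [SensorArray-class].
#' @param window sample span `c(first, last)`, 1-based inclusive; the span
#'   is trimmed so that (last - first) is a multiple of the keyframe stride.
#' @param priors a [priorSpec()] or NULL. Walking-kind problems without
#'   priors trigger an identifiability warning (the hip-center geometry is
#'   not identifiable from degenerate gait alone).
#' @param cfg a [noiseConfig()].
#' @param keyframeRate keyframe rate, Hz.
#' @param kind "calibration" or "walking".
#' @return an `EstimationProblem` list; `$counts` holds the bookkeeping.
#' @export
assembleProblem <- function(array, window = NULL, priors = NULL,
                            cfg = noiseConfig(), keyframeRate = 20,
                            kind = c("calibration", "walking")) {
  kind <- match.arg(kind)
  fs <- sampleRate(array)
  n <- length(array)
  if (is.null(window)) window <- c(1L, n)
  lo <- as.integer(window[1]); hi <- as.integer(window[2])
  if (hi <= lo) stop("argument error: empty window")
  m <- fs / keyframeRate
  if (abs(m - round(m)) > 1e-9)
    stop("argument error: keyframeRate must divide the sampling rate")
  m <- as.integer(round(m))
  K <- (hi - lo) %/% m + 1L
  if (K < 2) stop("argument error: window shorter than one keyframe interval")
  hi <- lo + (K - 1L) * m
  if (kind == "walking" && is.null(priors))
    warning("walking-kind problem without hip-center priors: ",
            "medial/lateral hip-center placement may be non-identifiable")
  ids <- imuPlacements()
  gyroL <- list(); accelL <- list()
  for (id in ids) {
    rec <- recordings(array)[[id]]
    rows <- lo:(hi - 1L)
    gyroL[[id]] <- rec@gyro[rows, , drop = FALSE]
    accelL[[id]] <- rec@accel[rows, , drop = FALSE]
  }
  jcN <- jointCenterNames(); axN <- hingeAxisNames()
  joints <- t(vapply(jointNames(), function(j) {
    sn <- jointSensors(j)
    c(match(sn[1], ids), match(sn[2], ids),
      match(paste0(j, "_prox"), jcN), match(paste0(j, "_dist"), jcN),
      match(paste0(j, "_prox"), axN), match(paste0(j, "_dist"), axN))
  }, numeric(6)))
  storage.mode(joints) <- "integer"
  sigHinge <- vapply(jointNames(), function(j)
    switch(sub("_[rl]$", "", j), knee = cfg$sigmaHingeKnee,
           hip = cfg$sigmaHingeHip, ankle = cfg$sigmaHingeAnkle),
    numeric(1))
  # the loose hip pseudo-hinge is a walking-task augmentation (it pins the
  # lumbar-thigh heading relation during near-1-DOF gait); the calibration
  # motion deliberately explores all 3 hip DOFs, where a hinge model - even
  # a loose one - would bias the geometry, so it is disabled there
  hingeUse <- rep(1L, 6)
  if (kind == "calibration")
    hingeUse[grepl("^hip", jointNames())] <- 0L
  hipPrior <- NULL
  if (!is.null(priors)) {
    nm <- hipConnectedNames()
    W <- lapply(priors$covs, function(C) chol(solve(C)))
    hipPrior <- list(idx = match(nm, jcN),
                     mean = do.call(rbind, priors$means[nm]),
                     W = unname(W[nm]))
  }
  counts <- list(
    nUnknowns = 7L * (9L * K + 6L) + 72L,
    nInertialIntervals = 7L * (K - 1L),
    nJointCenterBlocks = 6L * K,
    nHingeBlocks = sum(hingeUse) * K,
    nUnitNorm = 12L,
    nPriorBlocks = if (is.null(hipPrior)) 0L else 4L,
    nResiduals = 7L * (K - 1L) * 9L + 6L * K * 3L + sum(hingeUse) * K * 3L +
      12L + (if (is.null(hipPrior)) 0L else 12L) + 7L + 42L + 36L + 36L)
  structure(list(
    K = K, m = m, dt = 1 / fs, kind = kind,
    window = c(lo, hi), kfSamples = lo + (seq_len(K) - 1L) * m,
    times = timestamps(array)[lo + (seq_len(K) - 1L) * m],
    sensors = ids, gyro = unname(gyroL), accel = unname(accelL),
    sigGyro = cfg$sigmaGyro, sigAccel = cfg$sigmaAccel,
    sigJc = cfg$sigmaJc, sigUnit = 1e-3,
    sigHinge = unname(sigHinge), hingeUse = hingeUse, joints = joints,
    hipPrior = hipPrior, gaugeSensor = match("lumbar", ids),
    sigGp = 1e-3, sigGv = 1e-3, sigGy = 1e-3,
    sigBgPrior = cfg$sigmaBiasGyro, sigBaPrior = cfg$sigmaBiasAccel,
    sigJcPrior = 0.5, sigAxPrior = 0.3,
    grav = cfg$gravity, counts = counts, cfg = cfg,
    array = array, keyframeRate = keyframeRate),
    class = "EstimationProblem")
}

#' @exportS3Method base::print
print.EstimationProblem <- function(x, ...) {
  cat(sprintf("EstimationProblem (%s): %d keyframes x 7 sensors, %d unknowns, %d residual rows\n",
              x$kind, x$K, x$counts$nUnknowns, x$counts$nResiduals))
  invisible(x)
}

# default initial guess: leveling + dead-reckoning, then heading/lever-arm
# alignment (alignInit); nominal (sensor x) hinge axes
defaultInit <- function(problem, align = TRUE, bg0 = NULL, ba0 = NULL) {
  st <- initializeStates(problem$array, problem$keyframeRate,
                         window = problem$window)
  init <- list(q = lapply(st, function(s) s@q),
               v = lapply(st, function(s) s@v),
               p = lapply(st, function(s) s@p),
               bg = matrix(0, 7, 3), ba = matrix(0, 7, 3),
               jc = matrix(0, 12, 3),
               ax = matrix(rep(c(1, 0, 0), each = 12), 12, 3))
  if (align) init <- alignInit(problem, init, bg0 = bg0, ba0 = ba0)
  init
}

#' Randomize the calibration part of an initial guess
#'
#' Draws joint-center initial values uniformly from a cube of half-width
#' `jcBox` and perturbs hinge axes by random rotations up to `axisNoiseDeg`.
#' Used to probe identifiability: parameters the data do not constrain stay
#' near their randomized starting values.
#'
#' @param problem an `EstimationProblem`.
#' @param seed integer.
#' @param jcBox half-width, m. @param axisNoiseDeg max axis perturbation.
#' @export
randomizeInit <- function(problem, seed, jcBox = 0.1, axisNoiseDeg = 10) {
  init <- defaultInit(problem)
  withSeed(seed * 31L + 5L, {
    init$jc <- matrix(stats::runif(36, -jcBox, jcBox), 12, 3)
    for (j in 1:12) {
      axn <- stats::rnorm(3); axn <- axn / sqrt(sum(axn^2))
      ang <- stats::runif(1, 0, axisNoiseDeg * pi / 180)
      R <- so3Exp(axn * ang)
      init$ax[j, ] <- as.numeric(R %*% init$ax[j, ])
    }
    init
  })
}

# pack a Solution back into a params list (for re-solving after the drift
# correction rotates part of the state)
solutionToParams <- function(problem, solution) {
  tr <- solution@trajectories
  list(q = lapply(tr, function(s) s@q),
       v = lapply(tr, function(s) s@v),
       p = lapply(tr, function(s) s@p),
       bg = do.call(rbind, lapply(tr, function(s) s@bg)),
       ba = do.call(rbind, lapply(tr, function(s) s@ba)),
       jc = do.call(rbind, jointCenters(solution@calibration)),
       ax = do.call(rbind, hingeAxes(solution@calibration)))
}

retractParams <- function(params, delta, K) {
  perSensor <- 9 * K + 6
  for (s in 1:7) {
    off <- (s - 1) * perSensor
    d <- matrix(delta[off + seq_len(9 * K)], ncol = 9, byrow = TRUE)
    params$q[[s]] <- quatNormalize(quatMult(params$q[[s]],
                                            quatExp(d[, 1:3, drop = FALSE])))
    params$v[[s]] <- params$v[[s]] + d[, 4:6, drop = FALSE]
    params$p[[s]] <- params$p[[s]] + d[, 7:9, drop = FALSE]
    params$bg[s, ] <- params$bg[s, ] + delta[off + 9 * K + 1:3]
    params$ba[s, ] <- params$ba[s, ] + delta[off + 9 * K + 4:6]
  }
  C0 <- 7 * perSensor
  params$jc <- params$jc + matrix(delta[C0 + 1:36], 12, 3, byrow = TRUE)
  params$ax <- params$ax + matrix(delta[C0 + 36 + 1:36], 12, 3, byrow = TRUE)
  params
}

#' Solve an assembled problem with Levenberg-Marquardt
#'
#' Terminates on an absolute cost change of 1e-6 or less between accepted
#' iterations, a relative change of 1e-4 or less, or 10,000 iterations,
#' whichever fires first; the firing criterion is recorded.
#'
#' @param problem from [assembleProblem()].
#' @param init optional initial params (default [defaultInit()] internally).
#' @param maxIterations iteration cap.
#' @param absTol,relTol convergence tolerances on the objective.
#' @param computeCov also compute 3 x 3 covariance blocks of the
#'   joint-center vectors at the optimum (Gauss-Newton approximation).
#' @param verbose print per-iteration cost.
#' @return a [Solution-class].
#' @export
solveLM <- function(problem, init = NULL, maxIterations = 10000,
                    absTol = 1e-6, relTol = 1e-4, computeCov = FALSE,
                    verbose = FALSE) {
  params <- if (is.null(init)) defaultInit(problem) else init
  problem$jcPriorCenter <- params$jc
  # rotation components of the step vector (for the trust-region cap)
  K <- problem$K
  perSensor <- 9L * K + 6L
  rotMask <- logical(7L * perSensor + 72L)
  for (s in 0:6)
    rotMask[s * perSensor + rep((0:(K - 1)) * 9L, each = 3L) + 1:3] <- TRUE
  ev <- .wk_eval(problem, params, TRUE)
  if (!all(is.finite(ev$r)))
    stop("initialization error: non-finite residual at the initial guess")
  cost <- 0.5 * sum(ev$r^2)
  lambda <- 1e-6
  iter <- 0L
  reason <- "max_iterations"
  costTrace <- cost
  ch <- NULL
  repeat {
    J <- Matrix::sparseMatrix(i = ev$i, j = ev$j, x = ev$x,
                              dims = c(ev$nR, ev$nP))
    A <- Matrix::forceSymmetric(Matrix::crossprod(J), uplo = "U")
    grad <- as.numeric(Matrix::crossprod(J, ev$r))
    D <- Matrix::Diagonal(x = pmax(Matrix::diag(A), 1e-8))
    accepted <- FALSE
    nReject <- 0L
    while (!accepted) {
      iter <- iter + 1L
      Ad <- A + lambda * D
      ok <- TRUE
      ch <- tryCatch(Matrix::Cholesky(Ad, LDL = FALSE, super = TRUE),
                     error = function(e) { ok <<- FALSE; NULL })
      if (!ok) { lambda <- lambda * 10; nReject <- nReject + 1L; next }
      delta <- as.numeric(Matrix::solve(ch, -grad))
      # trust-region cap: a rotation update beyond ~20 deg (or any huge
      # component) is outside the linearization's validity and can hop
      # into spurious twisted basins; scale the whole step down instead
      maxRot <- max(abs(delta[rotMask]), 0)
      scale <- min(1, 0.35 / max(maxRot, 1e-12), 3 / max(abs(delta)))
      if (scale < 1) delta <- delta * scale
      cand <- retractParams(params, delta, problem$K)
      rNew <- .wk_eval(problem, cand, FALSE)$r
      costNew <- 0.5 * sum(rNew^2)
      if (is.finite(costNew) && costNew <= cost) {
        accepted <- TRUE
        dCost <- cost - costNew
        params <- cand
        lambda <- max(lambda / 3, 1e-12)
        if (verbose)
          message(sprintf("iter %d cost %.8g (d %.3g, lambda %.1g)",
                          iter, costNew, dCost, lambda))
        costPrev <- cost
        cost <- costNew
        costTrace <- c(costTrace, cost)
        if (dCost <= absTol) { reason <- "absolute"; break }
        if (dCost / max(costPrev, .Machine$double.eps) <= relTol) {
          reason <- "relative"; break
        }
      } else {
        # a rejected step whose cost change is below the absolute
        # tolerance means the iteration is at a numerical stationary
        # point: the between-iteration change in error cannot fall
        # further, so the absolute criterion fires
        if (is.finite(costNew) && abs(costNew - cost) <= absTol) {
          reason <- "absolute"
          break
        }
        lambda <- lambda * 10
        nReject <- nReject + 1L
        if (nReject >= 30L || lambda > 1e14) { reason <- "stalled"; break }
      }
      if (iter >= maxIterations) { reason <- "max_iterations"; break }
    }
    if (accepted && !reason %in% c("absolute", "relative") &&
        iter < maxIterations) {
      ev <- .wk_eval(problem, params, TRUE)
      next
    }
    break
  }
  buildSolution(problem, params, cost, reason, iter, costTrace, computeCov)
}

buildSolution <- function(problem, params, cost, reason, iter, costTrace,
                          computeCov = FALSE) {
  ids <- problem$sensors
  traj <- list()
  for (s in seq_along(ids)) {
    clamp <- function(b, lim) pmax(pmin(b, lim - 1e-9), -(lim - 1e-9))
    traj[[ids[s]]] <- StateTrajectory(ids[s], problem$times,
      q = quatNormalize(params$q[[s]]), p = params$p[[s]], v = params$v[[s]],
      bg = clamp(params$bg[s, ], 0.1), ba = clamp(params$ba[s, ], 1.0))
  }
  jc <- params$jc; ax <- params$ax
  # normalize axes; tie-break each joint's axis pair so the proximal-frame
  # axis points along its nominal (initialization) direction
  ax <- ax / sqrt(rowSums(ax^2))
  jcN <- jointCenterNames()
  for (j in jointNames()) {
    ip <- match(paste0(j, "_prox"), jcN); idist <- match(paste0(j, "_dist"), jcN)
    if (ax[ip, 1] < 0) { ax[ip, ] <- -ax[ip, ]; ax[idist, ] <- -ax[idist, ] }
  }
  covs <- list()
  if (computeCov) covs <- calibCovariance(problem, params)
  # lever arms beyond 1 m are nonphysical; clamp with a diagnostic note
  # rather than abort (typically a sign of an underexcited window)
  notes <- character()
  nrm <- sqrt(rowSums(jc^2))
  if (any(nrm >= 1)) {
    bad <- which(nrm >= 1)
    jc[bad, ] <- jc[bad, ] * (0.99 / nrm[bad])
    notes <- sprintf("jc_bound_clamped_%s", jcN[bad])
  }
  calib <- CalibrationParameters(
    jointCenters = stats::setNames(lapply(seq_len(12), function(i) jc[i, ]), jcN),
    hingeAxes = stats::setNames(lapply(seq_len(12), function(i) ax[i, ]),
                                hingeAxisNames()),
    covariances = covs, notes = notes)
  new("Solution", trajectories = traj, calibration = calib, cost = cost,
      convergence = reason, iterations = as.numeric(iter),
      telemetry = list(costTrace = costTrace, counts = problem$counts))
}

# Gauss-Newton covariance blocks of the joint-center vectors at the optimum
calibCovariance <- function(problem, params) {
  ev <- .wk_eval(problem, params, TRUE)
  J <- Matrix::sparseMatrix(i = ev$i, j = ev$j, x = ev$x,
                            dims = c(ev$nR, ev$nP))
  A <- Matrix::forceSymmetric(Matrix::crossprod(J), uplo = "U")
  # small diag-scaled ridge keeps flat directions finite without moving
  # the well-determined ones; escalate if the factorization still fails
  D <- Matrix::Diagonal(x = pmax(Matrix::diag(A), 1))
  ch <- NULL
  for (ridge in c(1e-10, 1e-7, 1e-4)) {
    ch <- tryCatch(Matrix::Cholesky(A + ridge * D, LDL = FALSE,
                                    super = TRUE),
                   error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch)) stop("covariance factorization failed")
  C0 <- 7 * (9 * problem$K + 6)
  E <- Matrix::sparseMatrix(i = C0 + 1:36, j = 1:36, x = 1,
                            dims = c(ev$nP, 36))
  X <- as.matrix(Matrix::solve(ch, E))[C0 + 1:36, , drop = FALSE]
  covs <- list()
  jcN <- jointCenterNames()
  for (i in seq_len(12)) {
    idx <- (i - 1) * 3 + 1:3
    covs[[jcN[i]]] <- (X[idx, idx] + t(X[idx, idx])) / 2
  }
  covs
}

#' Run the full self-calibration on a calibration-motion recording
#'
#' Solves the complete problem (no hip-center priors) on a recording of a
#' motion that excites all hip degrees of freedom, and extracts the
#' calibration with Gauss-Newton covariances. If the recorded motion does
#' not sufficiently explore a hip's rotational DOFs (smallest singular value
#' of the centered lumbar-thigh relative-rotation excitation below
#' `excitationThreshold` radians), an identifiability warning is attached to
#' the result and raised.
#'
#' @param array a [SensorArray-class].
#' @param cfg a [noiseConfig()].
#' @param keyframeRate Hz.
#' @param init optional initial parameter guess.
#' @param excitationThreshold rad.
#' @return [CalibrationParameters-class] with covariances.
#' @export
runCalibration <- function(array, cfg = noiseConfig(), keyframeRate = 20,
                           init = NULL, excitationThreshold = 0.05) {
  problem <- assembleProblem(array, priors = NULL, cfg = cfg,
                             keyframeRate = keyframeRate,
                             kind = "calibration")
  st <- initializeStates(array, keyframeRate)
  checkInit <- list(q = lapply(st, function(s) s@q))
  notes <- character()
  for (side in c("r", "l")) {
    sMin <- hipExcitation(checkInit, match("lumbar", problem$sensors),
                          match(paste0("thigh_", side), problem$sensors))
    if (sMin < excitationThreshold) {
      notes <- c(notes, sprintf("underexcited_hip_%s", side))
      warning(sprintf(
        "identifiability warning: hip_%s excitation %.3f rad below %.3f; ",
        side, sMin, excitationThreshold),
        "hip-center vectors may be non-identifiable")
    }
  }
  if (!is.null(init)) {
    sol <- solveLM(problem, init = init, computeCov = TRUE)
  } else {
    sol <- solveProgressive(array, window = c(1L, length(array)),
                            priors = NULL, cfg = cfg,
                            keyframeRate = keyframeRate,
                            kind = "calibration",
                            computeCov = TRUE)$solution
  }
  calib <- sol@calibration
  initialize(calib, notes = c(calib@notes, notes))
}

# extend a converged solution on a shorter prefix window into an initial
# guess for a longer window sharing the same start: the solved part is kept
# and the extension is propagated through the raw measurements with the
# estimated biases (drift over one extension stage stays small because the
# biases are already estimated from the solved prefix)
extendInit <- function(probNew, probOld, sol) {
  params <- solutionToParams(probOld, sol)
  m <- probNew$m; dt <- probNew$dt
  Kold <- probOld$K; Knew <- probNew$K
  g <- c(0, 0, -probNew$grav)
  for (s in seq_along(probNew$sensors)) {
    gy <- probNew$gyro[[s]]; ac <- probNew$accel[[s]]
    i0 <- (Kold - 1L) * m           # raw rows already covered
    rows <- (i0 + 1L):nrow(gy)
    bg <- params$bg[s, ]; ba <- params$ba[s, ]
    qExt <- .wk_deadreckon(params$q[[s]][Kold, ],
                           rbind(sweep(gy[rows, , drop = FALSE], 2, bg),
                                 c(0, 0, 0)), dt)
    nE <- length(rows)
    aW <- quatRotate(qExt[seq_len(nE), , drop = FALSE],
                     sweep(ac[rows, , drop = FALSE], 2, ba))
    aW <- sweep(aW, 2, -g)          # add gravity
    vLast <- params$v[[s]][Kold, ]; pLast <- params$p[[s]][Kold, ]
    vExt <- rbind(matrix(vLast, 1), matrix(vLast, nE, 3, byrow = TRUE) +
                    apply(aW * dt, 2, cumsum))
    pExt <- matrix(pLast, nE + 1L, 3, byrow = TRUE) +
      rbind(0, apply(vExt[seq_len(nE), , drop = FALSE] * dt, 2, cumsum))
    kfLocal <- seq(m + 1L, nE + 1L, by = m)   # new keyframes past the old end
    params$q[[s]] <- rbind(params$q[[s]], qExt[kfLocal, , drop = FALSE])
    params$v[[s]] <- rbind(params$v[[s]], vExt[kfLocal, , drop = FALSE])
    params$p[[s]] <- rbind(params$p[[s]], pExt[kfLocal, , drop = FALSE])
    stopifnot(nrow(params$q[[s]]) == Knew)
  }
  params
}

# progressive window-growing solve: short prefix first (where open-loop
# initialization is reliable), then repeatedly extend and re-solve; avoids
# the bias-drift divergence of initializing a long window open loop
solveProgressive <- function(array, window, priors, cfg, keyframeRate, kind,
                             stageT = c(10, 20, 40), bg0 = NULL, ba0 = NULL,
                             computeCov = FALSE, initOverride = NULL) {
  fs <- sampleRate(array)
  lo <- window[1]; hi <- window[2]
  his <- unique(pmin(c(lo + as.integer(round(stageT * fs)), hi), hi))
  his <- his[his > lo]
  sol <- NULL; probOld <- NULL
  for (i in seq_along(his)) {
    last <- i == length(his)
    prob <- assembleProblem(array, window = c(lo, his[i]), priors = priors,
                            cfg = cfg, keyframeRate = keyframeRate,
                            kind = kind)
    init <- if (is.null(sol)) {
      if (!is.null(initOverride)) initOverride
      else defaultInit(prob, bg0 = bg0, ba0 = ba0)
    } else extendInit(prob, probOld, sol)
    sol <- solveLM(prob, init = init, computeCov = computeCov && last)
    probOld <- prob
  }
  list(problem = probOld, solution = sol)
}

# smallest singular value (rad) of the centered relative-rotation samples
# between two sensors' initial orientation guesses
hipExcitation <- function(init, sA, sB) {
  rel <- quatLog(quatMult(quatConj(init$q[[sA]]), init$q[[sB]]))
  rel <- sweep(rel, 2, colMeans(rel))
  sv <- svd(rel / sqrt(nrow(rel)))$d
  sv[3]
}

#' Estimate walking kinematics window by window
#'
#' Cuts the recording into near-equal windows, solves each independently
#' (with the hip-center priors from the calibration task), optionally runs
#' the hip internal/external-rotation drift correction per window, and
#' concatenates the per-window trajectories. Priors are mandatory: without
#' them the hip geometry is not identifiable from degenerate walking.
#'
#' @param array a [SensorArray-class].
#' @param priors a [priorSpec()] (e.g. from [priorsFromCalibration()]).
#' @param cfg a [noiseConfig()].
#' @param nWindows number of windows (default 60 for a 30-min recording).
#' @param keyframeRate Hz.
#' @param driftCorrection run [correctionLoop()] per window.
#' @param mStar drift slope threshold, deg/s.
#' @param verbose print progress.
#' @return a concatenated [Solution-class]; per-window calibrations and
#'   drift telemetry in `@telemetry$windows`.
#' @export
runWalking <- function(array, priors, cfg = noiseConfig(), nWindows = 60,
                       keyframeRate = 20, driftCorrection = TRUE,
                       mStar = 0.05, verbose = FALSE) {
  if (is.null(priors) || !inherits(priors, "walkimuPriors"))
    stop("missing priors: walking estimation requires hip-center priors ",
         "from a calibration task")
  plan <- planWindows(array, nWindows)
  n <- length(array)
  wins <- list()
  bgPrev <- NULL; baPrev <- NULL
  m <- as.integer(round(sampleRate(array) / keyframeRate))
  for (w in seq_len(plan$nWindows)) {
    lo <- plan$bounds[w, 1] + 1L
    # snap the window start up to the global keyframe grid so that
    # concatenated keyframes stay uniformly spaced across boundaries
    lo <- 1L + as.integer(ceiling((lo - 1L) / m)) * m
    hi <- min(plan$bounds[w, 2] + 1L, n)
    res <- solveProgressive(array, window = c(lo, hi), priors = priors,
                            cfg = cfg, keyframeRate = keyframeRate,
                            kind = "walking",
                            stageT = if (w == 1) c(10) else numeric(),
                            bg0 = bgPrev, ba0 = baPrev)
    problem <- res$problem
    sol <- res$solution
    if (driftCorrection) sol <- correctionLoop(problem, sol, mStar = mStar)
    if (verbose)
      message(sprintf("window %d/%d: cost %.4g (%s, %d iters)", w,
                      plan$nWindows, sol@cost, sol@convergence,
                      as.integer(sol@iterations)))
    bgPrev <- do.call(rbind, lapply(sol@trajectories, function(s) s@bg))
    baPrev <- do.call(rbind, lapply(sol@trajectories, function(s) s@ba))
    wins[[w]] <- sol
  }
  concatenateSolutions(wins)
}

# concatenate per-window solutions; duplicate boundary keyframes dropped,
# calibration averaged element-wise across windows
concatenateSolutions <- function(wins) {
  if (length(wins) == 1L) {
    sol <- wins[[1]]
    sol@telemetry$windows <- list(perWindow(wins[[1]]))
    return(sol)
  }
  ids <- names(wins[[1]]@trajectories)
  traj <- list()
  for (id in ids) {
    parts <- lapply(wins, function(s) s@trajectories[[id]])
    times <- parts[[1]]@times; q <- parts[[1]]@q
    p <- parts[[1]]@p; v <- parts[[1]]@v
    for (w in 2:length(parts)) {
      drop1 <- abs(parts[[w]]@times[1] - times[length(times)]) < 1e-9
      sel <- if (drop1) -1L else TRUE
      times <- c(times, parts[[w]]@times[sel])
      q <- rbind(q, parts[[w]]@q[sel, , drop = FALSE])
      p <- rbind(p, parts[[w]]@p[sel, , drop = FALSE])
      v <- rbind(v, parts[[w]]@v[sel, , drop = FALSE])
    }
    traj[[id]] <- StateTrajectory(id, times, q, p, v,
                                  bg = parts[[1]]@bg, ba = parts[[1]]@ba)
  }
  jcAll <- lapply(wins, function(s) do.call(rbind, jointCenters(s@calibration)))
  axAll <- lapply(wins, function(s) do.call(rbind, hingeAxes(s@calibration)))
  jc <- Reduce(`+`, jcAll) / length(wins)
  ax <- Reduce(`+`, axAll) / length(wins)
  ax <- ax / sqrt(rowSums(ax^2))
  calib <- CalibrationParameters(
    jointCenters = stats::setNames(lapply(seq_len(12), function(i) jc[i, ]),
                                   jointCenterNames()),
    hingeAxes = stats::setNames(lapply(seq_len(12), function(i) ax[i, ]),
                                hingeAxisNames()))
  new("Solution", trajectories = traj, calibration = calib,
      cost = sum(vapply(wins, function(s) s@cost, numeric(1))),
      convergence = "windows",
      iterations = sum(vapply(wins, function(s) s@iterations, numeric(1))),
      telemetry = list(windows = lapply(wins, perWindow)))
}

perWindow <- function(sol) {
  list(cost = sol@cost, convergence = sol@convergence,
       iterations = sol@iterations, calibration = sol@calibration,
       drift = sol@telemetry$drift)
}
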