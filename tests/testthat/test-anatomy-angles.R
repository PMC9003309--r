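crossRowsTest <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("pcsFromAxes builds right-handed orthonormal frames", {
  expect_equal(pcsFromAxes(c(1, 0, 0), c(0, 0, 1)), diag(3))
  expect_equal(pcsFromAxes(c(0, 1, 0), c(0, 0, 1)),
               rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1)))
  expect_error(pcsFromAxes(c(1, 0, 0), c(1e-9, 0, 0)), "degenerate-axes")
  # property: 1000 random non-parallel pairs
  set.seed(13)
  for (i in 1:1000) {
    x <- rnorm(3); z <- rnorm(3)
    s <- sqrt(sum(crossRowsTest(x, z)^2)) / sqrt(sum(x^2) * sum(z^2))
    if (s <= 1e-6) next
    B <- pcsFromAxes(x, z)
    expect_lt(max(abs(B %*% t(B) - diag(3))), 1e-9)
    expect_lt(abs(det(B) - 1), 1e-9)
    xh <- x / sqrt(sum(x^2))
    expect_lt(max(abs(B[1, ] - xh)), 1e-12)   # first row parallel to x
  }
})

test_that("pelvicVertical averages the gravity direction", {
  mkTraj <- function(q) StateTrajectory("lumbar", seq(0, 1, by = 0.05),
                                        q, matrix(0, 21, 3), matrix(0, 21, 3))
  # level and static, sensor z up
  qI <- matrix(rep(c(1, 0, 0, 0), 21), ncol = 4, byrow = TRUE)
  expect_equal(pelvicVertical(mkTraj(qI)), c(0, 0, 1), tolerance = 1e-12)
  # pitched 30 deg about sensor x: vertical moves in the sensor y-z plane
  q30 <- matrix(rep(quatExp(c(30 * pi / 180, 0, 0)), 21), ncol = 4,
                byrow = TRUE)
  expect_equal(pelvicVertical(mkTraj(q30)), c(0, sin(pi / 6), cos(pi / 6)),
               tolerance = 1e-9)
  # oscillating +/- 10 deg about a zero-mean: within 0.6 deg of static
  ang <- 10 * pi / 180 * sin(seq(0, 2 * pi, length.out = 21))
  qOsc <- quatExp(cbind(ang, 0, 0))
  v <- pelvicVertical(mkTraj(qOsc))
  expect_lt(acos(min(1, sum(v * c(0, 0, 1)))) * 180 / pi, 0.6)
  expect_error(pelvicVertical(mkTraj(qI), window = c(5, 6)),
               "argument error")
})

test_that("pelvisOrientation flips with swapped hip centers", {
  jc <- setNames(lapply(jointCenterNames(), function(n) c(0, 0, -0.1)),
                 jointCenterNames())
  jc$hip_r_prox <- c(0.1, 0, -0.05)
  jc$hip_l_prox <- c(-0.1, 0, -0.05)
  ax <- setNames(lapply(hingeAxisNames(), function(n) c(1, 0, 0)),
                 hingeAxisNames())
  calib <- CalibrationParameters(jc, ax)
  B <- pelvisOrientation(calib, c(0, 0, 1))
  expect_equal(B, diag(3), tolerance = 1e-12)
  jc2 <- jc
  jc2$hip_r_prox <- jc$hip_l_prox
  jc2$hip_l_prox <- jc$hip_r_prox
  B2 <- pelvisOrientation(CalibrationParameters(jc2, ax), c(0, 0, 1))
  expect_equal(B2[1, ], -B[1, ])
  expect_equal(B2[2, ], -B[2, ])
  expect_equal(B2[3, ], B[3, ])
  jc3 <- jc
  jc3$hip_l_prox <- jc$hip_r_prox
  expect_error(pelvisOrientation(CalibrationParameters(jc3, ax), c(0, 0, 1)),
               "degenerate-axes")
})

test_that("segment frames recover the true mounts from true calibration", {
  tr <- smallCalibTrial()
  sf <- segmentFrames(truthCalibration(tr))
  for (id in c("thigh_r", "shank_l")) {
    m <- tr@meta$mounts[[id]]
    # the anatomical frame maps sensor to segment coordinates, i.e. it
    # equals the mount rotation (sensor -> segment)
    expect_lt(rotAngleDeg(sf[[id]], quatToMatrix(m$q)), 0.5)
  }
})

test_that("Cardan decomposition round-trips random triples exactly", {
  set.seed(21)
  for (i in 1:200) {
    fe <- runif(1, -80, 80); aa <- runif(1, -40, 40); ie <- runif(1, -80, 80)
    for (side in c("right", "left")) {
      s <- if (side == "left") -1 else 1
      R <- walkimu:::rotX(fe * pi / 180) %*%
        walkimu:::rotY(s * aa * pi / 180) %*%
        walkimu:::rotZ(s * ie * pi / 180)
      ang <- cardanE1FloatingE3(R, side)
      expect_equal(unname(ang), c(fe, aa, ie), tolerance = 1e-9)
    }
  }
  expect_equal(unname(cardanE1FloatingE3(diag(3))), c(0, 0, 0))
  expect_equal(unname(cardanE1FloatingE3(walkimu:::rotX(pi / 6))),
               c(30, 0, 0), tolerance = 1e-9)
  expect_error(cardanE1FloatingE3(walkimu:::rotY(pi / 2)), "singularity")
})

test_that("degenerate gait yields near-zero hip ab/ad and int/ext", {
  tr <- cachedTrial("degenWalk", generateTrial(
    "walking", seed = 9, duration = 6, fs = 100, degenerate1dof = TRUE,
    noise = noiselessSpec()))
  priors <- priorsFromCalibration(truthCalibration(tr), fallbackSd = 0.005)
  prob <- assembleProblem(sensorArray(tr), priors = priors,
                          keyframeRate = 20, kind = "walking")
  sol <- solveLM(prob)
  ha <- hipAngles(sol)
  kf <- prob$kfSamples
  for (side in c("r", "l")) {
    est <- ha[[paste0("hip_", side)]]
    tru <- truthAngles(tr)[[paste0("hip_", side)]]
    expect_lt(sqrt(mean((est@fe - tru@fe[kf])^2)), 1)
    expect_lt(max(abs(est@aa)), 0.5)
    expect_lt(max(abs(est@ie)), 0.5)
  }
})
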