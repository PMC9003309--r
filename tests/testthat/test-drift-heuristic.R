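test_that("linear drift fit recovers exact lines and ignores sinusoids", {
  t <- seq(0, 30, by = 0.05)
  fit <- fitLinearDrift(0.02 * t + 5, t = t)
  expect_equal(fit$m, 0.02, tolerance = 1e-12)
  expect_equal(fit$b, 5, tolerance = 1e-12)
  expect_lt(max(abs(fit$e)), 1e-12)

  fitC <- fitLinearDrift(rep(7, length(t)), t = t)
  expect_lt(abs(fitC$m), 1e-12)
  expect_equal(fitC$b, 7, tolerance = 1e-12)

  # a zero-mean oscillation that is even about the window center over
  # whole periods is orthogonal to the trend, so the line is untouched
  tP <- seq(0, 30, by = 0.01)
  pert <- 4 * cos(2 * pi * (tP - 15))
  pert <- pert - mean(pert)
  fitS <- fitLinearDrift(0.1 * tP + 2 + pert, t = tP)
  expect_equal(fitS$m, 0.1, tolerance = 1e-9)
  expect_equal(fitS$b, 2, tolerance = 1e-9)

  expect_error(fitLinearDrift(c(1, 2), t = c(1, 1)), "constant time")
  expect_error(fitLinearDrift(1, t = 1), "argument error")
})

test_that("flattenDrift removes exactly the fitted ramp", {
  t <- seq(0, 10, by = 0.1)
  y <- 0.02 * t + 5
  fit <- fitLinearDrift(y, t = t)
  expect_equal(flattenDrift(fit), rep(5, length(t)), tolerance = 1e-12)
  # idempotent once the slope is zero
  fit2 <- fitLinearDrift(flattenDrift(fit), t = t)
  expect_equal(flattenDrift(fit2), flattenDrift(fit), tolerance = 1e-12)
  expect_equal(mean(flattenDrift(fit)), fit$b, tolerance = 1e-12)
})

test_that("rotating the distal chain changes hip I/E but not knee angles", {
  sw <- smallWalkSolution()
  sol <- sw$solution
  ka0 <- kneeAngles(sol)
  ha0 <- hipAngles(sol)
  fakeFit <- structure(list(m = 1.0, b = 0, e = 0, side = "right"),
                       class = "DriftFit")
  rot <- rotateDistalChain(sol, "right", fakeFit)
  ka1 <- kneeAngles(rot)
  ha1 <- hipAngles(rot)
  expect_lt(max(abs(ka1$knee_r@fe - ka0$knee_r@fe)), 1e-9)
  expect_lt(max(abs(ka1$knee_l@fe - ka0$knee_l@fe)), 1e-9)
  expect_lt(max(abs(ha1$hip_l@ie - ha0$hip_l@ie)), 1e-9)   # contralateral
  expect_gt(max(abs(ha1$hip_r@ie - ha0$hip_r@ie)), 1)      # target changed
  # zero slope leaves the solution bit-identical
  zeroFit <- structure(list(m = 0, b = 0, e = 0, side = "right"),
                       class = "DriftFit")
  expect_identical(rotateDistalChain(sol, "right", zeroFit), sol)
})

test_that("an induced vertical-axis ramp shows up one-to-one in hip I/E", {
  # upright pose with the hip rotating purely about the vertical: the
  # decomposed internal/external rotation equals the heading ramp
  sw <- smallWalkSolution()
  sol <- sw$solution
  ha0 <- hipAngles(sol)
  fit <- structure(list(m = -0.8, b = 0, e = 0, side = "right"),
                   class = "DriftFit")
  rot <- rotateDistalChain(sol, "right", fit)
  ha1 <- hipAngles(rot)
  induced <- ha1$hip_r@ie - ha0$hip_r@ie
  t <- ha0$hip_r@t
  # thigh long axis is not exactly vertical during gait, so allow a small
  # projection tolerance
  slope <- stats::coef(stats::lm(induced ~ t))[2]
  expect_equal(unname(slope), 0.8, tolerance = 0.1)
})

test_that("correction loop exits immediately when slopes are below m*", {
  sw <- smallWalkSolution()
  out <- correctionLoop(sw$problem, sw$solution, mStar = 0.5)
  expect_equal(out@cost, sw$solution@cost)
  expect_identical(out@trajectories, sw$solution@trajectories)
  expect_equal(out@telemetry$drift$passes, 1L)
  expect_true(out@telemetry$drift$settled)
})

test_that("correction loop removes an injected heading ramp", {
  sw <- smallWalkSolution()
  sol <- sw$solution
  ha0 <- hipAngles(sol)
  inj <- structure(list(m = 1.0, b = 0, e = 0, side = "right"),
                   class = "DriftFit")
  drifted <- rotateDistalChain(sol, "right", inj)
  drifted@cost <- 0.5 * sum(walkimu:::.wk_eval(
    sw$problem, walkimu:::solutionToParams(sw$problem, drifted), FALSE)$r^2)
  ieRmse <- function(s) {
    ha <- hipAngles(s)
    sqrt(mean((ha$hip_r@ie - ha0$hip_r@ie)^2))
  }
  before <- ieRmse(drifted)
  # a 6-s fixture cannot resolve slopes to the 30-s default threshold, so
  # the loop runs with a proportionally wider m*
  corrected <- correctionLoop(sw$problem, drifted, mStar = 0.15)
  fitR <- fitLinearDrift(hipAngles(corrected)$hip_r)
  fitL <- fitLinearDrift(hipAngles(corrected)$hip_l)
  expect_lt(abs(fitR$m), 0.15)
  expect_lt(abs(fitL$m), 0.15)
  expect_lt(ieRmse(corrected), 0.5 * before)
  expect_lte(corrected@cost, drifted@cost + 1e-9)
})
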