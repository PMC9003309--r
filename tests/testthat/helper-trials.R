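# Shared fixtures: small synthetic trials, generated once per test run and
# cached. Sizes are deliberately modest (short durations, 100 Hz) so the
# whole suite stays fast; the acceptance tests use the full study-scale
# conditions.

.trialCache <- new.env(parent = emptyenv())

cachedTrial <- function(key, expr) {
  if (!exists(key, envir = .trialCache)) assign(key, expr, envir = .trialCache)
  get(key, envir = .trialCache)
}

smallCalibTrial <- function() cachedTrial("calib", generateTrial(
  "calibration", seed = 2, duration = 12, fs = 100, noise = noiselessSpec()))

smallWalkTrial <- function() cachedTrial("walk", generateTrial(
  "walking", seed = 1, duration = 6, fs = 100, noise = noiselessSpec()))

# a converged solution on a short noiseless walking window, with
# truth-derived priors
smallWalkSolution <- function() cachedTrial("walksol", {
  tr <- smallWalkTrial()
  priors <- priorsFromCalibration(truthCalibration(tr), fallbackSd = 0.005)
  prob <- assembleProblem(sensorArray(tr), priors = priors,
                          keyframeRate = 20, kind = "walking")
  list(trial = tr, problem = prob, solution = solveLM(prob))
})

truthSolution <- function(trial, keyframeRate = 20) {
  arr <- sensorArray(trial)
  fs <- sampleRate(arr)
  m <- as.integer(round(fs / keyframeRate))
  n <- length(arr)
  kf <- seq(1L, n, by = m)
  traj <- lapply(truthStates(trial), function(st)
    StateTrajectory(st@sensorId, st@times[kf], st@q[kf, , drop = FALSE],
                    st@p[kf, , drop = FALSE], st@v[kf, , drop = FALSE]))
  new("Solution", trajectories = traj,
      calibration = truthCalibration(trial), cost = 0,
      convergence = "truth", iterations = 0, telemetry = list())
}

vecErrMm <- function(a, b) 1000 * sqrt(sum((a - b)^2))

axisErrDeg <- function(a, b) acos(min(1, abs(sum(a * b)))) * 180 / pi
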