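# Detection and correction of linear drift in hip internal/external
# rotation.
#
# Magnetometer-free estimation leaves the heading relationship between the
# lumbar and thigh sensors only weakly constrained (through the loose hip
# hinge model), so the derived hip internal/external rotation angle can
# drift slowly and trap the optimizer in a poor local minimum. The
# correction: fit a line to each hip's I/E angle over the window, and if a
# slope exceeds the threshold m*, subtract the ramp by rigidly rotating that
# side's thigh-shank-foot states about the vertical axis through the hip
# center, then re-optimize from the corrected state. Repeated until both
# slopes are below m* and successive converged costs differ by less than 1%.

#' Ordinary least-squares drift fit of an angle series
#'
#' Fits `y = m x + b + e` with x = time.
#'
#' @param series a [JointAngleSeries-class] (its I/E channel is used) or a
#'   numeric vector of angles (then `t` must be given).
#' @param t times, s (taken from the series when omitted).
#' @param channel which channel of a series to fit.
#' @param mStar slope threshold carried along, deg/s.
#' @return a `DriftFit` list: slope `m` (deg/s), intercept `b` (deg),
#'   residuals `e` (deg), `side`, `mStar`.
#' @export
fitLinearDrift <- function(series, t = NULL, channel = "ie", mStar = 0.05) {
  side <- NA_character_
  if (is(series, "JointAngleSeries")) {
    y <- angleChannel(series, channel)
    t <- series@t
    side <- series@side
  } else y <- as.numeric(series)
  if (length(y) < 2) stop("argument error: need >= 2 samples")
  if (length(t) != length(y)) stop("argument error: t and y lengths differ")
  if (max(t) - min(t) < .Machine$double.eps)
    stop("argument error: constant time vector")
  fit <- stats::lm.fit(cbind(1, t), y)
  structure(list(m = unname(fit$coefficients[2]),
                 b = unname(fit$coefficients[1]),
                 e = unname(fit$residuals), t = t, y = y,
                 side = side, mStar = mStar), class = "DriftFit")
}

#' @exportS3Method base::print
print.DriftFit <- function(x, ...) {
  cat(sprintf("DriftFit (%s): m = %.4f deg/s, b = %.2f deg, n = %d\n",
              x$side, x$m, x$b, length(x$e)))
  invisible(x)
}

#' Remove the fitted slope from an angle series
#'
#' Sets the slope to zero holding intercept and residuals fixed:
#' `y' = b + e = y - m x`.
#'
#' @param fit a `DriftFit`.
#' @return corrected angle vector, deg.
#' @export
flattenDrift <- function(fit) {
  stopifnot(inherits(fit, "DriftFit"))
  fit$b + fit$e
}

#' Rotate one leg's distal chain to induce drift-free hip rotation
#'
#' At each keyframe the side's thigh, shank and foot states are rotated by
#' `-m t_k` (the fitted ramp, converted to radians) about the world vertical
#' axis through that side's current hip-center point; lumbar and
#' contralateral states are untouched. Rotating thigh, shank and foot
#' together preserves knee and ankle angles exactly; only the hip
#' internal/external rotation (heading) changes.
#'
#' @param solution a [Solution-class].
#' @param side "right" or "left".
#' @param fit the side's `DriftFit`.
#' @return rotated [Solution-class].
#' @export
rotateDistalChain <- function(solution, side = c("right", "left"), fit) {
  side <- match.arg(side)
  if (fit$m == 0) return(solution)
  sfx <- if (side == "right") "r" else "l"
  lum <- solution@trajectories[["lumbar"]]
  sHip <- jointCenters(solution@calibration)[[paste0("hip_", sfx, "_prox")]]
  hip <- lum@p + quatRotate(lum@q, sHip)          # world hip center per kf
  phi <- -fit$m * pi / 180 * lum@times            # rad per keyframe
  qz <- quatExp(cbind(0, 0, phi))
  traj <- solution@trajectories
  for (id in paste0(c("thigh_", "shank_", "foot_"), sfx)) {
    st <- traj[[id]]
    q <- quatNormalize(quatMult(qz, st@q))
    p <- hip + quatRotate(qz, st@p - hip)
    v <- quatRotate(qz, st@v)
    traj[[id]] <- StateTrajectory(id, st@times, q, p, v, st@bg, st@ba)
  }
  initialize(solution, trajectories = traj)
}

#' Drift detection / correction / re-optimization loop
#'
#' Steps per pass: (1) derive both hips' internal/external rotation series;
#' (2) fit a line to each; (3) if both |slope| < `mStar`, stop; otherwise
#' (4) flatten the offending ramps, (5) rotate the affected distal chains,
#' and (6) re-solve the window from the corrected state. The loop repeats
#' while successive converged costs differ by at least 1%, with a hard cap
#' of `maxPasses` passes (then the best-cost solution is returned with a
#' warning). The returned solution never costs more than the input.
#'
#' @param problem the window's `EstimationProblem`.
#' @param solution a converged [Solution-class] for that window.
#' @param mStar slope threshold, deg/s.
#' @param maxPasses oscillation guard.
#' @return a [Solution-class] with drift telemetry in
#'   `@telemetry$drift` (per-pass slopes, passes used).
#' @export
correctionLoop <- function(problem, solution, mStar = 0.05, maxPasses = 10) {
  cur <- solution
  best <- solution
  prevCost <- solution@cost
  slopes <- list()
  passed <- FALSE
  for (pass in seq_len(maxPasses)) {
    ha <- hipAngles(cur)
    fits <- list(right = fitLinearDrift(ha$hip_r, mStar = mStar),
                 left = fitLinearDrift(ha$hip_l, mStar = mStar))
    slopes[[pass]] <- c(right = fits$right$m, left = fits$left$m)
    if (abs(fits$right$m) < mStar && abs(fits$left$m) < mStar) {
      passed <- TRUE
      break
    }
    for (side in c("right", "left"))
      if (abs(fits[[side]]$m) >= mStar)
        cur <- rotateDistalChain(cur, side, fits[[side]])
    cur <- solveLM(problem, init = solutionToParams(problem, cur))
    if (cur@cost < best@cost) best <- cur
    rel <- abs(cur@cost - prevCost) / max(prevCost, .Machine$double.eps)
    prevCost <- cur@cost
    if (rel < 0.01) {
      # converged solutions less than 1% different: check slopes once more
      ha <- hipAngles(cur)
      fits <- list(right = fitLinearDrift(ha$hip_r, mStar = mStar),
                   left = fitLinearDrift(ha$hip_l, mStar = mStar))
      slopes[[pass + 1]] <- c(right = fits$right$m, left = fits$left$m)
      passed <- abs(fits$right$m) < mStar && abs(fits$left$m) < mStar
      break
    }
  }
  if (!passed && length(slopes) >= maxPasses)
    warning("drift correction did not settle within ", maxPasses,
            " passes; returning best-cost solution")
  out <- if (passed) cur else best
  if (out@cost > solution@cost + 1e-9) out <- solution
  out@telemetry$drift <- list(passes = length(slopes), slopes = slopes,
                              settled = passed)
  out
}
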