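# Comparison of estimated and reference joint angles.
#
# The estimator has no absolute heading/pelvis datum, so estimated angles
# carry a static offset against any external reference. The relative angle
# removes it: alpha_rel,k = alpha_k + mean(beta - alpha), after which
# mean(alpha_rel) = mean(beta) exactly. Errors are reported both ways:
# absolute RMSE (datum included) and relative RMSE / peak error (waveform
# only).

#' Shift a series by the constant mean difference from a reference
#'
#' @param alpha estimated angle series, deg.
#' @param beta reference angle series, deg, same length.
#' @return `alpha + mean(beta - alpha)`; its mean equals `mean(beta)`.
#' @export
relativeSeries <- function(alpha, beta) {
  if (length(alpha) != length(beta) || length(alpha) < 1)
    stop("argument error: series lengths differ or empty")
  alpha + mean(beta - alpha)
}

#' Compare an estimated angle series against a reference
#'
#' @param alpha,beta equal-length series, deg.
#' @param joint,side,channel optional labels carried into the result.
#' @return a `ComparisonResult` list: `absoluteRmse`, `relativeRmse`,
#'   `peakError` (max |alpha_rel - beta|), `meanOffset` (the constant
#'   added), `nSamples`.
#' @export
compareSeries <- function(alpha, beta, joint = NA, side = NA, channel = NA) {
  if (length(alpha) != length(beta) || length(alpha) < 1)
    stop("argument error: series lengths differ or empty")
  off <- mean(beta - alpha)
  rel <- alpha + off
  structure(list(joint = joint, side = side, channel = channel,
                 absoluteRmse = sqrt(mean((alpha - beta)^2)),
                 relativeRmse = sqrt(mean((rel - beta)^2)),
                 peakError = max(abs(rel - beta)),
                 meanOffset = off, nSamples = length(alpha)),
            class = "ComparisonResult")
}

#' @exportS3Method base::print
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s %s %s: abs RMSE %.2f, rel RMSE %.2f, peak %.2f deg (n=%d)\n",
              x$joint, x$side, x$channel, x$absoluteRmse, x$relativeRmse,
              x$peakError, x$nSamples))
  invisible(x)
}

#' Average comparison results across sides
#'
#' Mirrors the reporting style of averaging the right and left leg.
#'
#' @param results list of `ComparisonResult`.
#' @return named numeric vector of side-averaged metrics.
#' @export
sideAverage <- function(results) {
  f <- function(field) mean(vapply(results, `[[`, numeric(1), field))
  c(absoluteRmse = f("absoluteRmse"), relativeRmse = f("relativeRmse"),
    peakError = f("peakError"))
}

#' Range of motion of an angle series
#'
#' @param series numeric angles, deg.
#' @param cycles optional `GaitCycleSet`; when given, returns one ROM per
#'   gait cycle instead of the whole-task max - min.
#' @export
rangeOfMotion <- function(series, cycles = NULL) {
  if (length(series) < 1) stop("argument error: empty series")
  if (is.null(cycles)) return(max(series) - min(series))
  vapply(seq_len(nrow(cycles$cycles)), function(i) {
    idx <- (cycles$cycles[i, 1] + 1L):cycles$cycles[i, 2]
    max(series[idx]) - min(series[idx])
  }, numeric(1))
}

#' Segment gait cycles at knee maximum flexion
#'
#' Detects local maxima of the reference knee flexion angle, gated by a
#' minimum separation and a minimum topographic prominence, and assigns each
#' sample a linearly interpolated phase (0-100 % between consecutive
#' events). The gait cycle is defined to start and end at knee maximum
#' flexion (approximately toe off).
#'
#' @param kneeReference reference knee flexion series, deg.
#' @param fs sampling rate of the series, Hz.
#' @param minSeparation minimum event spacing, s.
#' @param minProminence minimum peak prominence, deg.
#' @return a `GaitCycleSet` list: `events` (sample indices, 1-based),
#'   `cycles` (half-open 0-based index ranges), `phase` (percent per
#'   sample, NA outside complete cycles).
#' @export
detectCycles <- function(kneeReference, fs, minSeparation = 0.6,
                         minProminence = 20) {
  y <- as.numeric(kneeReference)
  n <- length(y)
  if (n < 3) stop("segmentation error: series too short")
  d <- diff(y)
  cand <- which(d[-1] < 0 & d[-(n - 1)] >= 0) + 1L
  if (!length(cand)) stop("segmentation error: no local maxima found")
  prom <- vapply(cand, function(i) peakProminence(y, i), numeric(1))
  keep <- cand[prom >= minProminence]
  # enforce separation, keeping higher peaks first
  keep <- keep[order(-y[keep])]
  sel <- integer()
  minGap <- minSeparation * fs
  for (i in keep)
    if (!length(sel) || min(abs(sel - i)) >= minGap) sel <- c(sel, i)
  events <- sort(sel)
  if (length(events) < 2)
    stop("segmentation error: fewer than 2 gait events detected")
  cycles <- cbind(start = events[-length(events)] - 1L,
                  end = events[-1] - 1L)
  phase <- rep(NA_real_, n)
  for (i in seq_len(nrow(cycles))) {
    idx <- (cycles[i, 1] + 1L):cycles[i, 2]
    phase[idx] <- (idx - idx[1]) / (cycles[i, 2] - cycles[i, 1]) * 100
  }
  list(events = events, cycles = cycles, phase = phase)
}

# topographic prominence of the peak at index i: height above the higher of
# the two key saddles toward the nearest higher terrain (or series ends)
peakProminence <- function(y, i) {
  n <- length(y)
  leftHigher <- which(y[seq_len(i - 1)] > y[i])
  lo <- if (length(leftHigher)) max(leftHigher) else 1L
  leftMin <- min(y[lo:i])
  rightHigher <- which(y[(i + 1):n] > y[i])
  hi <- if (length(rightHigher)) i + min(rightHigher) else n
  rightMin <- min(y[i:hi])
  y[i] - max(leftMin, rightMin)
}

#' Gait-phase profile of knee angle error
#'
#' Bins the signed error (estimate minus reference) by gait phase across
#' cycles, summarizes stance and swing, and computes the signed hysteresis
#' area of the mean estimate-vs-reference loop (a pure offset has zero
#' area; phase-dependent over/underestimation yields a nonzero loop).
#'
#' @param imuKnee,refKnee aligned knee flexion series, deg.
#' @param cycles from [detectCycles()] on the reference.
#' @param nBins number of phase bins (>= 4).
#' @param stancePhase phase window treated as stance, percent; the cycle
#'   starts at maximum flexion (about toe off), so swing occupies the early
#'   phase and stance the remainder. Supply generator or measured events
#'   through `detectCycles` for a data-driven split.
#' @return a `SoftTissueProfile` list: `binCenters`, `meanError` per bin,
#'   `stanceMean`, `swingMean`, `hysteresisArea` (deg^2), `nBins`.
#' @export
softTissueProfile <- function(imuKnee, refKnee, cycles, nBins = 20,
                              stancePhase = c(40, 100)) {
  if (nBins < 4) stop("argument error: nBins must be >= 4")
  if (length(imuKnee) != length(refKnee))
    stop("argument error: series lengths differ")
  ph <- cycles$phase
  ok <- !is.na(ph)
  err <- imuKnee - refKnee
  bin <- pmin(floor(ph[ok] / (100 / nBins)), nBins - 1) + 1L
  meanError <- vapply(seq_len(nBins), function(b)
    mean(err[ok][bin == b]), numeric(1))
  meanImu <- vapply(seq_len(nBins), function(b)
    mean(imuKnee[ok][bin == b]), numeric(1))
  meanRef <- vapply(seq_len(nBins), function(b)
    mean(refKnee[ok][bin == b]), numeric(1))
  binCenters <- (seq_len(nBins) - 0.5) * 100 / nBins
  inStance <- binCenters >= stancePhase[1] & binCenters < stancePhase[2]
  # shoelace area of the closed mean (ref, imu) loop
  xs <- c(meanRef, meanRef[1]); ys <- c(meanImu, meanImu[1])
  area <- 0.5 * sum(xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)])
  list(binCenters = binCenters, meanError = meanError,
       stanceMean = mean(meanError[inStance]),
       swingMean = mean(meanError[!inStance]),
       hysteresisArea = area, nBins = nBins, stancePhase = stancePhase)
}
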