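# Reading, writing, validating and windowing multi-sensor IMU recordings.
#
# CSV is the canonical exchange dialect: one file per sensor with a one-line
# header `t,gx,gy,gz,ax,ay,az`, times in seconds (re-referenced to start at
# 0), gyro in rad/s and accelerometer specific force in m/s^2.

#' Read one sensor's recording from CSV
#'
#' @param path path to a CSV file with columns `t,gx,gy,gz,ax,ay,az`.
#' @param sensorId placement label, one of [imuPlacements()].
#' @return an [ImuRecording-class]; the sampling rate is inferred from the
#'   median time step.
#' @export
readImuCsv <- function(path, sensorId) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  d <- utils::read.csv(path, check.names = TRUE)
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(d) < 2) stop("empty-input error: fewer than 2 samples in ", path)
  if (any(diff(d$t) <= 0))
    stop("sync error: timestamps not strictly increasing in ", path)
  ImuRecording(sensorId, d$t,
               gyro = as.matrix(d[, c("gx", "gy", "gz")]),
               accel = as.matrix(d[, c("ax", "ay", "az")]))
}

#' Write a recording to CSV at full float precision
#'
#' @param rec an [ImuRecording-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeImuCsv <- function(rec, path) {
  stopifnot(is(rec, "ImuRecording"))
  validObject(rec)
  d <- cbind(rec@t, rec@gyro, rec@accel)
  colnames(d) <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("I/O error: cannot open ", path, " for writing"))
  on.exit(close(con))
  writeLines(paste(colnames(d), collapse = ","), con)
  body <- apply(format(d, digits = 17, trim = TRUE, scientific = TRUE), 1,
                paste, collapse = ",")
  writeLines(body, con)
  invisible(path)
}

#' Assemble seven recordings into a synchronized SensorArray
#'
#' @param recs list of [ImuRecording-class], one per placement.
#' @return a [SensorArray-class].
#' @export
assembleArray <- function(recs) {
  ids <- unname(vapply(recs, function(r) r@sensorId, character(1)))
  if (!identical(sort(ids), sort(imuPlacements())))
    stop("topology error: need exactly one recording per placement, got: ",
         paste(sort(ids), collapse = ", "))
  names(recs) <- ids
  recs <- recs[imuPlacements()]
  t0 <- recs[[1]]@t
  for (r in recs[-1])
    if (length(r@t) != length(t0) || max(abs(r@t - t0)) > 1e-6)
      stop("sync error: recording '", r@sensorId,
           "' is not on the common timebase")
  new("SensorArray", recordings = recs, duration = t0[length(t0)] - t0[1])
}

#' Plan near-equal-length analysis windows
#'
#' Tiles the sample index range [0, N) into `nWindows` contiguous half-open
#' ranges whose lengths differ by at most one sample. Long recordings are
#' optimized per window to bound time and memory; the per-window results are
#' concatenated afterwards.
#'
#' @param array a [SensorArray-class] (or an integer sample count).
#' @param nWindows number of windows.
#' @return list with `nWindows` and an `nWindows` x 2 matrix `bounds` of
#'   0-based half-open index ranges.
#' @export
planWindows <- function(array, nWindows) {
  n <- if (is(array, "SensorArray")) length(array) else as.integer(array)
  nWindows <- as.integer(nWindows)
  if (nWindows < 1) stop("argument error: nWindows must be >= 1")
  if (nWindows > n) stop("argument error: more windows than samples")
  # distribute the remainder over the first windows
  base <- n %/% nWindows
  extra <- n %% nWindows
  len <- rep(base, nWindows) + c(rep(1L, extra), rep(0L, nWindows - extra))
  end <- cumsum(len)
  bounds <- cbind(start = c(0L, end[-nWindows]), end = end)
  list(nWindows = nWindows, bounds = bounds)
}
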