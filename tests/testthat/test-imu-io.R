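makeRec <- function(n = 10, fs = 200, id = "lumbar") {
  set.seed(3)
  ImuRecording(id, t = (seq_len(n) - 1) / fs,
               gyro = matrix(rnorm(3 * n), ncol = 3),
               accel = matrix(rnorm(3 * n, 0, 1) + rep(c(0, 0, 9.81),
                                                       each = n), ncol = 3))
}

test_that("CSV round trip preserves all fields to 1e-12", {
  rec <- makeRec(25)
  path <- tempfile(fileext = ".csv")
  writeImuCsv(rec, path)
  expect_equal(length(readLines(path)), 26L)  # header + rows
  back <- readImuCsv(path, "lumbar")
  expect_equal(back@t, rec@t, tolerance = 1e-12)
  expect_equal(back@gyro, rec@gyro, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back@accel, rec@accel, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back@fs, rec@fs, tolerance = 1e-9)
})

test_that("reader infers rate and rejects malformed input", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("t,gx,gy,gz,ax,ay,az",
               "0,0,0,0,0,0,9.81",
               "0.005,0,0,0,0,0,9.81",
               "0.010,0,0,0,0,0,9.81"), path)
  rec <- readImuCsv(path, "lumbar")
  expect_equal(rec@fs, 200, tolerance = 1e-9)

  writeLines(c("t,gx,gy,gz,ax,ay,az",
               "0,0,0,0,0,0,9.81",
               "0.005,0,0,0,0,0,9.81",
               "0.004,0,0,0,0,0,9.81"), path)
  expect_error(readImuCsv(path, "lumbar"), "sync error")

  writeLines(c("t,gx,gy,gz,ax,ay", "0,0,0,0,0,0"), path)
  expect_error(readImuCsv(path, "lumbar"), "format error")

  writeLines(c("t,gx,gy,gz,ax,ay,az", "0,0,0,0,0,0,9.81"), path)
  expect_error(readImuCsv(path, "lumbar"), "empty-input")
})

test_that("assembleArray enforces topology and synchrony", {
  recs <- lapply(imuPlacements(), function(id) makeRec(10, id = id))
  arr <- assembleArray(recs)
  expect_s4_class(arr, "SensorArray")
  expect_error(assembleArray(recs[-1]), "topology error")
  shifted <- recs
  bad <- recs[[2]]
  shifted[[2]] <- ImuRecording(bad@sensorId, bad@t + 0.005, bad@gyro,
                               bad@accel, bad@fs)
  # t is re-referenced to 0 on construction, so shift one interior stamp
  tt <- bad@t; tt[5] <- tt[5] + 0.002
  expect_error(ImuRecording(bad@sensorId, tt, bad@gyro, bad@accel),
               "not uniform")
})

test_that("planWindows tiles the sample range near-equally", {
  p <- planWindows(360000L, 60)
  expect_equal(p$nWindows, 60L)
  expect_true(all(p$bounds[, 2] - p$bounds[, 1] == 6000L))  # ~30 s at 200 Hz
  expect_equal(planWindows(10L, 1)$bounds, cbind(start = 0L, end = 10L),
               ignore_attr = TRUE)
  p3 <- planWindows(10L, 3)
  expect_equal(sort(p3$bounds[, 2] - p3$bounds[, 1], decreasing = TRUE),
               c(4L, 3L, 3L))
  expect_error(planWindows(5L, 6), "argument error")
  # property: exact tiling for random sizes
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:5000, 1); k <- sample(1:min(n, 80), 1)
    b <- planWindows(n, k)$bounds
    expect_equal(unname(b[1, 1]), 0L)
    expect_equal(unname(b[nrow(b), 2]), as.integer(n))
    if (nrow(b) > 1) expect_equal(unname(b[-1, 1]), unname(b[-nrow(b), 2]))
    expect_lte(diff(range(b[, 2] - b[, 1])), 1L)
  }
})
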