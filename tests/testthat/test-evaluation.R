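test_that("relative series matches the reference mean exactly", {
  expect_equal(relativeSeries(c(0, 10), c(10, 20)), c(10, 20))
  a <- rnorm(50); expect_equal(relativeSeries(a, a), a)
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30, 3)
    expect_lt(abs(mean(relativeSeries(a, b)) - mean(b)), 1e-12)
  }
  expect_error(relativeSeries(1:3, 1:4), "argument error")
})

test_that("comparison metrics follow their definitions", {
  r <- compareSeries(c(0, 0), c(4, 4))
  expect_equal(r$absoluteRmse, 4)
  expect_equal(r$relativeRmse, 0)
  expect_equal(r$peakError, 0)

  r2 <- compareSeries(c(0, 0), c(3, -3))
  expect_equal(r2$absoluteRmse, 3)
  expect_equal(r2$relativeRmse, 3)
  expect_equal(r2$peakError, 3)

  r3 <- compareSeries(c(0, 0, 0), c(1, 2, 6))
  expect_equal(r3$meanOffset, 3)
  expect_equal(r3$peakError, 3)
  expect_equal(r3$relativeRmse, sqrt(14 / 3), tolerance = 1e-12)

  # invariants: relative <= absolute; peak >= relative RMSE; symmetry of RMS
  set.seed(6)
  for (i in 1:30) {
    a <- rnorm(40); b <- rnorm(40, 1)
    r <- compareSeries(a, b)
    expect_lte(r$relativeRmse, r$absoluteRmse + 1e-12)
    expect_gte(r$peakError, r$relativeRmse - 1e-12)
    expect_equal(r$absoluteRmse, compareSeries(b, a)$absoluteRmse)
  }
})

test_that("range of motion handles whole-task and per-cycle forms", {
  t <- seq(0, 10, by = 0.01)
  y <- 30 + 20 * sin(2 * pi * t)          # sweeps 10..50
  expect_equal(rangeOfMotion(y), 40, tolerance = 1e-6)
  expect_equal(rangeOfMotion(rep(3, 5)), 0)
  expect_error(rangeOfMotion(numeric()), "argument error")
  cyc <- detectCycles(y, fs = 100, minSeparation = 0.6, minProminence = 10)
  perCycle <- rangeOfMotion(y, cyc)
  expect_true(all(abs(perCycle - 40) < 0.1))
})

test_that("cycle detection finds sinusoid peaks at the right spacing", {
  t <- seq(0, 10, by = 0.01)
  y <- 30 + 20 * sin(2 * pi * t / 1.25)
  cyc <- detectCycles(y, fs = 100)
  expect_equal(diff(cyc$events), rep(125, length(cyc$events) - 1),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(detectCycles(rep(1, 500), fs = 100), "segmentation error")
  # phase is 0 at events and covers 0-100
  expect_equal(cyc$phase[cyc$events[1]], 0)
  expect_equal(max(cyc$phase, na.rm = TRUE), 100, tolerance = 1)
})

test_that("cycle count matches the generator on synthetic walking", {
  p <- gaitProfile(duration = 30, fs = 100, cadence = 100)
  y <- p@channels$knee_r[, 1]
  cyc <- detectCycles(y, fs = 100)
  # 25 full cycles -> 25 or 26 maxima depending on boundary alignment
  expect_equal(length(cyc$events), length(p@eventsR))
})

test_that("soft-tissue profile separates offset from hysteresis", {
  p <- gaitProfile(duration = 20, fs = 100, cadence = 100)
  ref <- p@channels$knee_r[, 1]
  cyc <- detectCycles(ref, fs = 100)
  same <- softTissueProfile(ref, ref, cyc)
  expect_true(all(abs(same$meanError) < 1e-12))
  expect_lt(abs(same$hysteresisArea), 1e-9)

  off <- softTissueProfile(ref + 2, ref, cyc)
  expect_true(all(abs(off$meanError - 2) < 1e-9))
  expect_lt(abs(off$hysteresisArea), 1e-6)   # a constant offset: no loop

  # phase-locked error produces the signed stance/swing pattern
  ph <- cyc$phase
  err <- ifelse(!is.na(ph) & ph >= 40, 3, -2)
  prof <- softTissueProfile(ref + ifelse(is.na(ph), 0, err), ref, cyc)
  expect_gt(prof$stanceMean, 0)
  expect_lt(prof$swingMean, 0)
  expect_error(softTissueProfile(ref, ref, cyc, nBins = 3), "argument error")
})
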