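---
title: "Magnetometer-free estimation of hip and knee kinematics: model and methods"
author: "walkimu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetometer-free estimation of hip and knee kinematics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Seven inertial measurement units (3-axis gyroscope + 3-axis accelerometer,
no magnetometer) are strapped to the sacrum/lumbar region, both thighs,
both shanks and both feet of a walking subject, sampled at 200 Hz. Neither
the orientation of each sensor on its segment nor its position relative to
the joint centers is known. The package jointly estimates, per analysis
window,

* a pose trajectory (orientation, velocity, position at 20 Hz keyframes)
  for every sensor in a shared gravity-aligned world frame,
* the static *calibration*: twelve sensor-to-joint-center lever arms and
  twelve hinge-axis directions, expressed in the sensor frames, and
* constant per-window gyro/accelerometer biases,

and derives 3-DOF hip angles (modified ISB/Wu convention) and knee angles
(Grood–Suntay joint coordinate system) from the result.

## The estimation model

All unknowns are stacked into one sparse nonlinear least-squares problem
solved per window with Levenberg–Marquardt. Residuals:

* **Inertial.** First-order strapdown propagation of the bias-corrected
  raw measurements between consecutive keyframes must reproduce the
  keyframe states (`R <- R Exp((w - bg) dt)`, `v <- v + (R(f - ba) + g) dt`,
  `p <- p + v dt`, gravity `g = (0, 0, -9.81)` m/s²). The residual is
  expressed in the earlier keyframe's frame and whitened by the
  measurement noise accumulated over the interval.
* **Joint center.** For each joint, the two flanking sensors must place
  the shared joint center at the same world point:
  `r = (p_A + R_A s_A) - (p_B + R_B s_B)`, with lever arms `s` among the
  unknowns. Scale `sigmaJc` (default 1 cm) represents joint model slop and
  soft tissue.
* **Hinge.** Both sensors flanking a joint must agree on the world
  direction of its hinge axis, `r = R_A a_A - R_B a_B`, with the axes
  among the unknowns. The knee is a good hinge (`sigmaHingeKnee` 0.05
  rad); the hip and ankle are modeled as *noisy hinges* (0.3 rad) during
  walking — loose enough to admit non-hinge motion, tight enough to pin
  the otherwise unidentifiable heading relation between the lumbar and
  thigh sensors during near-1-DOF gait. On the calibration motion, which
  deliberately explores all three hip DOFs, a hip hinge model of any
  stiffness biases the geometry, so the hip hinge is active only in
  walking-kind problems (measured >100 mm lever-arm bias before this
  gate).
* **Priors and gauge.** Gaussian priors on the four hip-connected lever
  arms (walking only, taken from the calibration task and inflated 4x),
  unit-norm residuals on the axes, weak zero-mean bias priors, a weak
  trust prior on all lever arms centered on the initialization (it bounds
  the structurally flat along-axis component of pure-hinge joint centers
  without shrinking identifiable components), and a gauge prior pinning
  the lumbar first-keyframe position, velocity and heading (inertial-only
  problems leave global translation, a constant-velocity offset, and
  heading undetermined; all derived angles are invariant to this gauge).

Convergence follows the windowed-smoothing convention: absolute cost
change ≤ 1e-6, relative change ≤ 1e-4, or 10,000 iterations, whichever
fires first. Jacobians are exact-sparsity central differences per residual
block (each block touches at most ~30 local coordinates), assembled in
compiled code; the normal equations are factorized with a supernodal
sparse Cholesky. Rotations live on the manifold: solver steps are applied
as right-multiplied exponential updates.

### Identifiability

Two practical non-identifiabilities shape the design:

1. During degenerate (pure flexion/extension) gait the medial/lateral
   placement of the hip centers is not identifiable: shifting both
   hip-connected lever arms of one side along the flexion axis leaves
   every residual unchanged. The hip-center priors from the calibration
   task restore identifiability; without them, estimates stay wherever
   the initialization put them (the package demonstrates both in its
   acceptance suite).
2. The relative heading between the lumbar and thigh sensors is only
   weakly determined during upright walking because the thigh-to-hip
   lever arms are nearly vertical. The noisy hip hinge supplies the
   missing information; remaining slow drift of the derived hip
   internal/external rotation is handled by the correction heuristic
   below.

A related *structural* property: for a pure hinge (the knee and ankle of
the simulator), the joint-center component along the hinge axis is flat —
"the" center is a line. The anatomical-frame construction is invariant to
it (the axis component of the proximal direction is removed by
orthogonalization), and the trust prior keeps it bounded; accuracy
statements therefore concern the hip-connected lever arms and the hinge
axes, not the along-axis hinge components.

### Initialization

Levenberg–Marquardt on this problem is extremely sensitive to the initial
guess: each sensor's heading, the lever arms, and the biases interact in
a long curved valley, and a naive start needs thousands of iterations.
Initialization proceeds in stages, all cheap:

1. leveling from the first 0.5 s of accelerometer data (roll/pitch from
   gravity, heading zero) and gyro dead-reckoning;
2. whole-window tilt refinement (for bounded motion the time-averaged
   world specific force must point up);
3. gyro-bias from a quiet-standing lead-in when the window starts static;
4. a chained coarse-to-fine 1-D heading grid per joint (the heading
   objective is multimodal);
5. an iterated reduced linear solve over initial positions/velocities,
   lever arms, and per-sensor small-rotation / rotation-rate /
   accelerometer-drift corrections, exploiting that for fixed headings
   the joint-center constraints are linear in everything else. The fits
   use only the first ~10 s (noise drifts double-integrated shapes as
   t^1.5).

Long windows are then solved by progressive growing (10 s, 20 s, 40 s,
full), each stage extending the previous solution through the raw
measurements with the estimated biases. Walking windows after the first
warm-start their biases from the previous window.

## Drift correction of hip internal/external rotation

Per window, after convergence: fit `y = m x + b + e` to both hips'
internal/external rotation series; if both |m| are below `mStar` (default
0.05 deg/s, configurable — about 1.5 deg over a 30-s window, well below
physiological range per window), stop. Otherwise set the slope to zero
(`y' = b + e`), induce `y'` by rotating the offending side's thigh, shank
and foot states about the world vertical through that side's hip center
(which changes hip axial rotation while leaving knee and ankle angles and
the vertical datum untouched), and re-optimize from this state. The loop
repeats while successive converged costs differ by at least 1% (the
compared quantity is the scalar objective), capped at 10 passes; the
returned solution never costs more than the input.

## Angle derivation

The pelvic frame is built from the estimated inter-hip-center direction
(right minus left lumbar lever arm) as the fixed +x axis and the
time-averaged world vertical expressed in the lumbar sensor frame as the
approximate proximal +z; +y completes the right-handed set. Thigh, shank
and foot frames come from the calibration: proximal +z along the segment's
two estimated joint centers, +x along the hinge axis. With +z proximal in
all segments, hip (Wu, modified) and knee (Grood–Suntay) angles reduce to
the same decomposition: flexion about the proximal x, ab/adduction about
the floating axis, axial rotation about the distal z, i.e. an intrinsic
x–y–z Cardan sequence; left-side ab/adduction and axial rotation are
negated so positive means adduction/internal rotation bilaterally. The
decomposition is singular only at ±90° ab/adduction, far outside gait.

Because the method has no absolute pelvis reference, hip angles carry a
static datum offset against any external reference — under trunk sway the
average-gravity proximal direction differs from the true pelvic axis by a
few degrees. Comparisons therefore report both absolute RMSE and
*relative* RMSE/peak error after shifting the estimate by the constant
mean difference (`alpha_rel = alpha + mean(beta - alpha)`), which removes
the datum and leaves waveform error.

## Evaluation

Gait cycles are delimited by knee maximum flexion events (approximately
toe off) of the reference series, detected as local maxima gated by
separation (default 0.6 s) and topographic prominence (default 20 deg);
phase is interpolated linearly 0–100% between events. The soft-tissue
profile bins the signed error (estimate − reference) by phase across
cycles, summarizes stance (default phase 40–100%, since the cycle starts
near toe off) and swing, and reports the signed shoelace area of the mean
estimate-vs-reference loop — a pure offset has zero area, phase-locked
over/underestimation a nonzero one. Whole-task range of motion is
max − min over the concatenated series (per-cycle available), and RMSE is
computed over the concatenated series, per channel, then side-averaged.

## The synthetic data generator

The generator is the package's test bed, not a population model:

* **Walking**: truncated-Fourier joint profiles (hip F/E ~40° range with
  a small second harmonic; hip ab/ad ±4° and int/ext ±3.5°, identically
  zero in the degenerate-1-DOF variant; a three-harmonic knee waveform
  with a ~60° swing peak and a ~20° loading-response bump; antiphase
  legs), small pelvic translation and orientation sway, cadence 100
  steps/min by default.
* **Calibration**: a vigorous motion exciting all three hip DOFs on both
  sides (hip flexion 0–60°, ab/ad ±25°, int/ext ±17°, knees 0–80°) with
  large trunk sway (roll ±20°, pitch ±16°, yaw ±25°, decimeter-level
  translations). Deep excursions are what condition the lever-arm and
  heading estimation; a timid calibration leaves the problem
  ill-conditioned — this mirrors the protocol requirement that the
  calibration "sufficiently explore" the hip DOFs.
* Both start with 2 s of quiet standing and blend into motion through a
  C1 time warp (warping time preserves waveform peak counts); the static
  span is realistic and makes the constant biases observable.
* **Sensor model**: mounts are seeded random orientation offsets (up to
  25°, emulating roughly-aligned strapping) and lever arms near plausible
  strap locations. The gyro sample is the exact per-step body-frame
  orientation increment and the accelerometer the exact forward-difference
  specific force, so first-order strapdown integration of the noiseless
  signals reproduces the true states to machine precision — noiseless
  closed-loop errors are attributable to the estimator alone. White noise
  (defaults: gyro 0.01 rad/s, accel 0.1 m/s² per sample, consumer-MEMS
  grade) and constant biases (uniform within ±0.01 rad/s, ±0.05 m/s²) are
  added from a seeded RNG; fixed seeds give bit-identical trials.
* **Soft tissue**: phase-locked rotation of the shank (or thigh) sensors
  about the segment flexion axis, smoothly windowed so the mount is
  nominal at the phase boundaries; it perturbs the recordings, not the
  truth.

What passing closed-loop tests do *not* show: real skin/muscle dynamics
(the injected artifact is a smooth phase-locked rotation), magnetic
disturbances (irrelevant — no magnetometer), joint translations, sensor
scale factors or axis misalignment, and real mocap reference error. The
simulator's knee and ankle are perfect hinges; real joints are not.

## Numerical choices and problem sizes

* Keyframes at 20 Hz with 10 raw samples per interval at 200 Hz; a 30-s
  window has ~4,200 state blocks.
* Whitening floors (`sigmaGyro` ≥ 1e-4 rad/s, `sigmaAccel` ≥ 1e-3 m/s²)
  keep noiseless problems well scaled.
* Numeric Jacobian step 1e-6 (central); LM damping is Marquardt-scaled
  (`A + lambda diag(A)`), with lambda divided by 3 on acceptance and
  multiplied by 10 on rejection. Steps are trust-region capped so no
  rotation component exceeds 0.35 rad: from a large-residual start a
  near-Gauss-Newton step can otherwise hop into a spurious basin in which
  a distal chain is twisted about a hinge with the free axis estimate
  following it. A weak nominal prior on the hinge axes (sd 0.3 per
  component about the sensor x axis, reflecting the roughly-aligned
  strapping) guards the same failure mode; its bias on well-excited axes
  is negligible (the hinge rows carry ~1e4 times more information).
* Hinge-axis sign: each estimated axis pair is flipped, as a pair, to a
  positive dot product with its nominal (initialization) direction —
  `a` and `-a` are equivalent for the residuals, and angle signs need a
  convention.
* Under-excitation detection: smallest singular value of the centered
  lumbar–thigh relative-rotation samples (from the dead-reckoned
  initialization) below 0.05 rad raises an identifiability warning.
* The test suite runs scaled-down fixtures (6–12 s at 100 Hz) for unit
  tests and the full study conditions (60-s calibration, 30-s walking
  windows, 200 Hz, 20 Hz keyframes) in the acceptance suite; those sizes
  are the package's validation conditions.

## Known limitations

* Hip angles are relative to an assumed vertical datum; absolute offsets
  of several degrees are expected and only relative errors are
  contractual.
* Hip internal/external rotation remains the weakest channel: the noisy
  hinge plus drift heuristic bound, but do not eliminate, heading-drift
  error — matching the method's published behavior.
* The along-axis component of hinge joint centers is reported but not
  accurate (structurally flat); ankle angles are derivable but carry no
  accuracy contract, and the foot anatomical frame is self-consistent
  rather than anatomical.
* World-frame position is gauge-fixed per window, not tracked; only
  relative/angular quantities are meaningful.
* CSV is the only exchange format (one file per sensor); there is no
  binary container support.
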