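# Initialization alignment.
#
# Gyro dead-reckoning fixes each sensor's orientation trajectory up to a
# constant rotation offset (plus bias-induced drift), and - given
# orientations - double-integrated specific force fixes its position
# trajectory up to an initial position and velocity (plus bias drift). The
# joint-center constraints therefore reduce to a small problem in per-sensor
# constant rotation offsets, rotation-rate errors (gyro bias), world
# accelerometer-bias drifts, initial positions/velocities, and the twelve
# joint-center vectors. Stages:
#   0. per-sensor gyro-bias guess from the window-mean angular rate (the
#      net rotation of bounded periodic motion is near zero);
#   1. whole-window tilt leveling: for bounded motion the time-averaged
#      world specific force must point up;
#   2. chained coarse-to-fine 1-D heading grid per joint (the heading
#      objective is multimodal, so each sensor is gridded against its
#      already-aligned proximal neighbour);
#   3. iterated linear least squares over initial positions/velocities,
#      joint-center vectors, and per-sensor correction families -
#      constant rotation delta0 (columns -[W]x), rotation rate delta1
#      (columns -[M]x with M the time-moment integral, capturing
#      gyro-bias gravity leakage), and world accel bias (columns t^2/2) -
#      refolding the corrections into orientations and bias estimates.
# The fits use only the first `alignT` seconds (noise drifts the
# double-integrated shapes as t^1.5); the rebuilt initial guess covers the
# whole window. Without this stage the full optimizer needs thousands of
# iterations through a curved heading/lever-arm valley.

# column-equilibrated ridge least squares: min ||X x + d||^2
scaledRidgeSolve <- function(X, d, ridge = 1e-8) {
  cn <- sqrt(colSums(X^2))
  cn[cn < 1e-12] <- 1
  Xs <- sweep(X, 2, cn, "/")
  xs <- solve(crossprod(Xs) + diag(ridge, ncol(X)), crossprod(Xs, -d))
  as.numeric(xs) / cn
}

skewColsInto <- function(X, rows1, rows2, rows3, w, sgn, base) {
  X[rows1, base + 2] <- X[rows1, base + 2] + sgn * w[, 3]
  X[rows1, base + 3] <- X[rows1, base + 3] - sgn * w[, 2]
  X[rows2, base + 1] <- X[rows2, base + 1] - sgn * w[, 3]
  X[rows2, base + 3] <- X[rows2, base + 3] + sgn * w[, 1]
  X[rows3, base + 1] <- X[rows3, base + 1] + sgn * w[, 2]
  X[rows3, base + 2] <- X[rows3, base + 2] - sgn * w[, 1]
  X
}

alignInit <- function(problem, init, maxKf = 240, outerIter = 6,
                      alignT = 12, bg0 = NULL, ba0 = NULL) {
  K <- problem$K; m <- problem$m; dt <- problem$dt
  tkf <- problem$times - problem$times[1]
  nRaw <- (K - 1L) * m + 1L
  tRaw <- (seq_len(nRaw) - 1L) * dt
  joints <- problem$joints
  hp <- problem$hipPrior
  g <- c(0, 0, -problem$grav)
  Kfit <- min(K, max(40L, as.integer(ceiling(alignT / (m * dt))) + 1L))

  # gyro-bias starting values: supplied warm start (from the previous
  # window), else estimated from a quiet-standing lead-in when the window
  # starts static, else zero; the delta1 / baW correction families below
  # refine them either way
  bg <- matrix(0, 7, 3)
  ba <- matrix(0, 7, 3)
  if (!is.null(bg0)) bg <- bg0
  if (!is.null(ba0)) ba <- ba0
  if (is.null(bg0)) {
    nStat <- min(as.integer(round(1 / dt)), nrow(problem$gyro[[1]]))
    for (s in 1:7) {
      gy <- problem$gyro[[s]][seq_len(nStat), , drop = FALSE]
      dev <- sweep(gy, 2, colMeans(gy))
      if (sqrt(mean(dev^2)) < 0.03) bg[s, ] <- colMeans(gy)
    }
  }

  deadReckonAll <- function(s, q0) {
    gy <- sweep(problem$gyro[[s]], 2, bg[s, ])
    .wk_deadreckon(q0, rbind(gy, gy[nrow(gy), ]), dt)
  }
  qRaw <- list()
  for (s in 1:7) {
    qr <- deadReckonAll(s, init$q[[s]][1, ])
    # stage 1: whole-window tilt leveling
    for (pass in 1:3) {
      aW <- quatRotate(qr[seq_len(nRaw - 1L), , drop = FALSE],
                       sweep(problem$accel[[s]], 2, ba[s, ]))
      fix <- levelingQuat(colMeans(aW))
      if (2 * acos(min(1, abs(fix[1]))) < 1e-7) break
      qr <- quatNormalize(quatMult(matrix(fix, 1)[rep(1, nRaw), ], qr))
    }
    qRaw[[s]] <- qr
  }

  stride <- max(1L, ceiling(Kfit / maxKf))
  kSub <- seq(1L, Kfit, by = stride)
  iRaw <- (kSub - 1L) * m + 1L
  tSub <- tkf[kSub]
  Ks <- length(kSub)

  # gravity-free shape integrals at raw rate (Euler, matching the
  # propagation model), with subsampled views: W = double integral of the
  # world-rotated bias-corrected specific force, M its time-moment
  integrateShapes <- function() {
    out <- list()
    for (s in 1:7) {
      aW <- quatRotate(qRaw[[s]][seq_len(nRaw - 1L), , drop = FALSE],
                       sweep(problem$accel[[s]], 2, ba[s, ]))
      vws <- rbind(0, apply(aW * dt, 2, cumsum))
      wps <- rbind(0, apply(vws[seq_len(nRaw - 1L), , drop = FALSE] * dt,
                            2, cumsum))
      vms <- rbind(0, apply(aW * tRaw[seq_len(nRaw - 1L)] * dt, 2, cumsum))
      mps <- rbind(0, apply(vms[seq_len(nRaw - 1L), , drop = FALSE] * dt,
                            2, cumsum))
      out[[s]] <- list(q = qRaw[[s]][iRaw, , drop = FALSE],
                       w = wps[iRaw, , drop = FALSE],
                       mm = mps[iRaw, , drop = FALSE],
                       vW = vws, Wp = wps)
    }
    out
  }
  sh <- integrateShapes()

  # ---- stage 2: chained heading grid ------------------------------------
  chainPsi <- rep(0, 7)
  chainP0 <- matrix(0, 7, 3); chainV0 <- matrix(0, 7, 3)
  rows1 <- seq(1, 3 * Ks, by = 3); rows2 <- rows1 + 1; rows3 <- rows1 + 2
  for (jn in c("hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l")) {
    j <- match(jn, jointNames())
    sA <- joints[j, 1]; sB <- joints[j, 2]
    qzA <- matrix(quatExp(c(0, 0, chainPsi[sA])), 1)[rep(1, Ks), ]
    qA <- quatMult(qzA, sh[[sA]]$q)
    termA <- matrix(chainP0[sA, ], Ks, 3, byrow = TRUE) +
      tSub %o% chainV0[sA, ] + quatRotate(qzA, sh[[sA]]$w)
    colsA <- lapply(1:3, function(c0) {
      e <- c(0, 0, 0); e[c0] <- 1; quatRotate(qA, e)
    })
    wA <- quatRotate(qzA, sh[[sA]]$w)
    mA <- quatRotate(qzA, sh[[sA]]$mm)
    pairRss <- function(psiB) {
      qzB <- matrix(quatExp(c(0, 0, psiB)), 1)[rep(1, Ks), ]
      qB <- quatMult(qzB, sh[[sB]]$q)
      wB <- quatRotate(qzB, sh[[sB]]$w)
      mB <- quatRotate(qzB, sh[[sB]]$mm)
      # unknowns: p0B, v0B, sA, sB, delta0 A/B, delta1 A/B, baW A/B
      npair <- 36L
      Xp <- matrix(0, 3 * Ks + 24L, npair)
      for (c0 in 1:3) {
        idx <- seq(c0, 3 * Ks, by = 3)
        Xp[cbind(idx, c0)] <- -1
        Xp[cbind(idx, 3 + c0)] <- -tSub
        Xp[cbind(idx, 30 + c0)] <- tSub^2 / 2        # baW of A
        Xp[cbind(idx, 33 + c0)] <- -tSub^2 / 2       # baW of B
      }
      for (c0 in 1:3) {
        e <- c(0, 0, 0); e[c0] <- 1
        colB <- quatRotate(qB, e)
        Xp[rows1, 6 + c0] <- colsA[[c0]][, 1]
        Xp[rows2, 6 + c0] <- colsA[[c0]][, 2]
        Xp[rows3, 6 + c0] <- colsA[[c0]][, 3]
        Xp[rows1, 9 + c0] <- -colB[, 1]
        Xp[rows2, 9 + c0] <- -colB[, 2]
        Xp[rows3, 9 + c0] <- -colB[, 3]
      }
      Xp <- skewColsInto(Xp, rows1, rows2, rows3, wA, 1, 12L)
      Xp <- skewColsInto(Xp, rows1, rows2, rows3, wB, -1, 15L)
      Xp <- skewColsInto(Xp, rows1, rows2, rows3, mA, 1, 18L)
      Xp <- skewColsInto(Xp, rows1, rows2, rows3, mB, -1, 21L)
      # soft penalties: corrections small, pair common modes pinned
      for (c0 in 1:12) Xp[3 * Ks + c0, 12 + c0] <- 30
      for (c0 in 1:6) Xp[3 * Ks + 12 + c0, 24 + c0] <- 1  # unused slack
      for (c0 in 1:6) Xp[3 * Ks + 18 + c0, 30 + c0] <- 2  # baW, m/s^2 scale
      dp <- numeric(3 * Ks + 24L)
      dif <- termA - wB
      dp[rows1] <- dif[, 1]; dp[rows2] <- dif[, 2]; dp[rows3] <- dif[, 3]
      xp <- scaledRidgeSolve(Xp, dp)
      list(rss = sum((Xp %*% xp + dp)^2), x = xp)
    }
    grid <- seq(-pi, pi, by = 15 * pi / 180)
    best <- grid[which.min(vapply(grid, function(p) pairRss(p)$rss,
                                  numeric(1)))]
    fine <- seq(best - 15 * pi / 180, best + 15 * pi / 180, by = pi / 180)
    psiB <- fine[which.min(vapply(fine, function(p) pairRss(p)$rss,
                                  numeric(1)))]
    xb <- pairRss(psiB)$x
    chainPsi[sB] <- psiB
    chainP0[sB, ] <- xb[1:3]
    chainV0[sB, ] <- xb[4:6]
  }
  for (s in 2:7) {
    qz <- matrix(quatExp(c(0, 0, chainPsi[s])), 1)[rep(1, nRaw), ]
    qRaw[[s]] <- quatNormalize(quatMult(qz, qRaw[[s]]))
  }

  # ---- stage 3: iterated linear refinement ------------------------------
  # unknown layout: sensors 2..7 (p0, v0) = 36; 12 jc = 36; then per all 7
  # sensors: delta0 (21), delta1 (21), baW (21)
  nx <- 36L + 36L + 63L
  colP0 <- function(s) (match(s, 2:7) - 1L) * 6L
  colJc <- function(v) 36L + (v - 1L) * 3L
  colD0 <- function(s) 72L + (s - 1L) * 3L
  colD1 <- function(s) 93L + (s - 1L) * 3L
  colBa <- function(s) 114L + (s - 1L) * 3L
  rowsPerJoint <- 3L * Ks
  # common rotations / rotation rates / accel drifts of all sensors are
  # exactly flat for the joint rows (gravity and drifts cancel pairwise);
  # pin the common modes so the leveled datum is kept
  nPen <- 9L + 63L + 36L
  nr <- 6L * rowsPerJoint + (if (!is.null(hp)) 12L else 0L) + nPen
  p0 <- matrix(0, 7, 3); v0 <- matrix(0, 7, 3)
  p0[2:7, ] <- chainP0[2:7, ]; v0[2:7, ] <- chainV0[2:7, ]
  jcEst <- matrix(0, 12, 3)
  for (outer in seq_len(outerIter)) {
    sh <- integrateShapes()
    X <- matrix(0, nr, nx)
    d <- numeric(nr)
    for (j in 1:6) {
      rows <- (j - 1L) * rowsPerJoint
      r1 <- rows + rows1; r2 <- rows + rows2; r3 <- rows + rows3
      for (ss in list(c(joints[j, 1], joints[j, 3], 1),
                      c(joints[j, 2], joints[j, 4], -1))) {
        s <- ss[1]; v <- ss[2]; sgn <- ss[3]
        for (c0 in 1:3) {
          e <- c(0, 0, 0); e[c0] <- 1
          Rcol <- quatRotate(sh[[s]]$q, e)
          X[r1, colJc(v) + c0] <- X[r1, colJc(v) + c0] + sgn * Rcol[, 1]
          X[r2, colJc(v) + c0] <- X[r2, colJc(v) + c0] + sgn * Rcol[, 2]
          X[r3, colJc(v) + c0] <- X[r3, colJc(v) + c0] + sgn * Rcol[, 3]
        }
        if (s > 1) {
          rr <- list(r1, r2, r3)
          for (c0 in 1:3) {
            X[rr[[c0]], colP0(s) + c0] <- X[rr[[c0]], colP0(s) + c0] + sgn
            X[rr[[c0]], colP0(s) + 3 + c0] <-
              X[rr[[c0]], colP0(s) + 3 + c0] + sgn * tSub
          }
        }
        for (c0 in 1:3) {
          rr <- list(r1, r2, r3)
          X[rr[[c0]], colBa(s) + c0] <-
            X[rr[[c0]], colBa(s) + c0] + sgn * tSub^2 / 2
        }
        X <- skewColsInto(X, r1, r2, r3, sh[[s]]$w, sgn, colD0(s))
        X <- skewColsInto(X, r1, r2, r3, sh[[s]]$mm, sgn, colD1(s))
        d[r1] <- d[r1] + sgn * sh[[s]]$w[, 1]
        d[r2] <- d[r2] + sgn * sh[[s]]$w[, 2]
        d[r3] <- d[r3] + sgn * sh[[s]]$w[, 3]
      }
    }
    if (!is.null(hp)) {
      for (i in 1:4) {
        v <- hp$idx[i]
        rows <- 6L * rowsPerJoint + (i - 1L) * 3L + 1:3
        X[rows, colJc(v) + 1:3] <- hp$W[[i]] * problem$sigJc
        d[rows] <- -as.numeric(hp$W[[i]] %*% hp$mean[i, ]) * problem$sigJc
      }
    }
    pen0 <- 6L * rowsPerJoint + (if (!is.null(hp)) 12L else 0L)
    for (c0 in 1:3) for (s in 1:7) {
      X[pen0 + c0, colD0(s) + c0] <- 100
      X[pen0 + 3 + c0, colD1(s) + c0] <- 100
      X[pen0 + 6 + c0, colBa(s) + c0] <- 100
    }
    # mild individual shrinkage for conditioning; joint-center shrinkage
    # keeps the along-axis null components of pure hinges near zero
    for (s in 1:7) for (c0 in 1:3) {
      X[pen0 + 9 + (s - 1) * 9 + c0, colD0(s) + c0] <- 3
      X[pen0 + 9 + (s - 1) * 9 + 3 + c0, colD1(s) + c0] <- 3
      X[pen0 + 9 + (s - 1) * 9 + 6 + c0, colBa(s) + c0] <- 1
    }
    for (v in 1:12) for (c0 in 1:3)
      X[pen0 + 72 + (v - 1) * 3 + c0, colJc(v) + c0] <- 1
    x <- scaledRidgeSolve(X, d)
    for (s in 2:7) {
      p0[s, ] <- x[colP0(s) + 1:3]
      v0[s, ] <- x[colP0(s) + 4:6]
    }
    jcEst <- matrix(x[36 + 1:36], 12, 3, byrow = TRUE)
    maxCorr <- 0
    for (s in 1:7) {
      d0 <- x[colD0(s) + 1:3]; d1 <- x[colD1(s) + 1:3]
      baW <- x[colBa(s) + 1:3]
      maxCorr <- max(maxCorr, abs(d0), abs(d1) * tkf[Kfit], abs(baW))
      # fold the rotation correction Exp(d0 + d1 t) into the orientations
      phi <- matrix(d0, nRaw, 3, byrow = TRUE) + tRaw %o% d1
      qRaw[[s]] <- quatNormalize(quatMult(quatExp(phi), qRaw[[s]]))
      # fold the corrections into body-frame bias estimates
      qs <- qRaw[[s]][iRaw, , drop = FALSE]
      bg[s, ] <- bg[s, ] - colMeans(quatRotate(quatConj(qs),
                                               matrix(d1, Ks, 3,
                                                      byrow = TRUE)))
      ba[s, ] <- ba[s, ] - colMeans(quatRotate(quatConj(qs),
                                               matrix(baW, Ks, 3,
                                                      byrow = TRUE)))
    }
    if (maxCorr < 1e-5) break
  }

  # rebuild a propagation-consistent initial guess at the keyframes
  sh <- integrateShapes()
  iKf <- (seq_len(K) - 1L) * m + 1L
  i1 <- iKf - 1L
  for (s in 1:7) {
    init$q[[s]] <- qRaw[[s]][iKf, , drop = FALSE]
    init$v[[s]] <- matrix(v0[s, ], K, 3, byrow = TRUE) +
      outer(i1 * dt, g, `*`) + sh[[s]]$vW[iKf, , drop = FALSE]
    init$p[[s]] <- matrix(p0[s, ], K, 3, byrow = TRUE) +
      outer(i1 * dt, v0[s, ], `*`) +
      outer(dt^2 * i1 * (i1 - 1) / 2, g, `*`) +
      sh[[s]]$Wp[iKf, , drop = FALSE]
  }
  init$bg <- bg
  init$ba <- ba
  # anatomical clamp: no sensor sits farther than ~0.4 m from its joint,
  # so an alignment fit that ran on weakly exciting data (e.g. mostly the
  # standing lead-in) cannot seed the solver - and the trust prior - with
  # nonphysical lever arms
  init$jc <- pmin(pmax(jcEst, -0.4), 0.4)
  init
}
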