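# Rotation utilities: unit quaternions (w, x, y, z) and SO(3) maps.
#
# Conventions used throughout the package:
#   * A state rotation R (or quaternion q) maps sensor-frame vectors into the
#     world frame: v_world = R %*% v_sensor.
#   * The world frame is right-handed with +z up; gravity is (0, 0, -g).
#   * Batch quaternions are stored as N x 4 matrices, batch vectors as N x 3.

#' Quaternion (Hamilton) product, vectorised
#'
#' @param q,p quaternions as length-4 vectors or N x 4 matrices (w, x, y, z).
#' @return N x 4 matrix (or length-4 vector if both inputs were vectors).
#' @export
quatMult <- function(q, p) {
  vec <- is.null(dim(q)) && is.null(dim(p))
  q <- rbind2mat4(q); p <- rbind2mat4(p)
  n <- max(nrow(q), nrow(p))
  if (nrow(q) == 1L && n > 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(p) == 1L && n > 1L) p <- p[rep(1L, n), , drop = FALSE]
  w1 <- q[, 1]; x1 <- q[, 2]; y1 <- q[, 3]; z1 <- q[, 4]
  w2 <- p[, 1]; x2 <- p[, 2]; y2 <- p[, 3]; z2 <- p[, 4]
  out <- cbind(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
  if (vec) out[1L, ] else out
}

rbind2mat4 <- function(q) {
  if (is.null(dim(q))) matrix(q, nrow = 1L) else as.matrix(q)
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @export
quatConj <- function(q) {
  if (is.null(dim(q))) return(c(q[1], -q[2], -q[3], -q[4]))
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

#' Exponential map: rotation vector(s) -> unit quaternion(s)
#'
#' @param phi rotation vector (length 3) or N x 3 matrix, radians.
#' @export
quatExp <- function(phi) {
  vec <- is.null(dim(phi))
  phi <- if (vec) matrix(phi, nrow = 1L) else as.matrix(phi)
  ang <- sqrt(rowSums(phi^2))
  half <- ang / 2
  # sinc(ang/2)/2, series for small angles
  s <- ifelse(ang > 1e-8, sin(half) / pmax(ang, .Machine$double.xmin),
              0.5 - ang^2 / 48)
  out <- cbind(cos(half), phi * s)
  if (vec) out[1L, ] else out
}

#' Logarithm map: unit quaternion(s) -> rotation vector(s), radians
#' @export
quatLog <- function(q) {
  vec <- is.null(dim(q))
  q <- rbind2mat4(q)
  # enforce w >= 0 to get the short rotation
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  w <- pmin(q[, 1], 1)
  vn <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vn, w)
  k <- ifelse(vn > 1e-12, ang / pmax(vn, .Machine$double.xmin), 2 / pmax(w, 1e-300))
  out <- q[, 2:4, drop = FALSE] * k
  if (vec) out[1L, ] else out
}

#' Rotate vectors by quaternions, vectorised
#'
#' @param q quaternion(s), @param v vector(s) N x 3; recycled to a common N.
#' @export
quatRotate <- function(q, v) {
  vec <- is.null(dim(q)) && is.null(dim(v))
  q <- rbind2mat4(q)
  v <- if (is.null(dim(v))) matrix(v, nrow = 1L) else as.matrix(v)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L && n > 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L && n > 1L) v <- v[rep(1L, n), , drop = FALSE]
  w <- q[, 1]; u <- q[, 2:4, drop = FALSE]
  # v' = v + 2 w (u x v) + 2 u x (u x v)
  uv <- crossRows(u, v)
  uuv <- crossRows(u, uv)
  out <- v + 2 * (w * uv) + 2 * uuv
  if (vec) out[1L, ] else out
}

# row-wise cross product of N x 3 matrices
crossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Quaternion -> 3 x 3 rotation matrix
#' @export
quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' 3 x 3 rotation matrix -> quaternion (w >= 0)
#' @export
matrixToQuat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' SO(3) exponential map: rotation vector -> rotation matrix
#' @param phi length-3 rotation vector, radians.
#' @export
so3Exp <- function(phi) quatToMatrix(quatExp(phi))

#' SO(3) logarithm map: rotation matrix -> rotation vector, radians
#' @export
so3Log <- function(R) quatLog(matrixToQuat(R))

#' Skew-symmetric (hat) matrix of a 3-vector
#' @keywords internal
so3Hat <- function(v) {
  matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

#' Elementary rotations about x, y, z (radians)
#' @keywords internal
rotX <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, 3, byrow = TRUE)
#' @rdname rotX
#' @keywords internal
rotY <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                           3, 3, byrow = TRUE)
#' @rdname rotX
#' @keywords internal
rotZ <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)

#' Heading (yaw) angle of a rotation, radians
#'
#' Yaw of the sensor x-axis projected into the world horizontal plane,
#' following the z-up world convention.
#' @keywords internal
headingOf <- function(R) atan2(R[2, 1], R[1, 1])

#' Normalize rows of a batch quaternion matrix
#' @export
quatNormalize <- function(q) {
  if (is.null(dim(q))) return(q / sqrt(sum(q^2)))
  q / sqrt(rowSums(q^2))
}

#' Angle between two rotations, degrees
#' @export
rotAngleDeg <- function(Ra, Rb) {
  sqrt(sum(so3Log(t(Ra) %*% Rb)^2)) * 180 / pi
}

#' Unit-normalize a 3-vector
#' @keywords internal
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}
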