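## Quaternion convention used throughout: Hamilton product, scalar-first
## (qw, qx, qy, qz), unit norm, mapping LOCAL sensor frame -> gravity-aligned
## GLOBAL frame (z up).  All helpers accept either a length-4 vector or an
## n x 4 matrix (one quaternion per sample).

.as_qmat <- function(q) {
  if (is.null(dim(q))) matrix(q, nrow = 1L) else as.matrix(q)
}

quat_normalize <- function(q) {
  qm <- .as_qmat(q)
  n <- sqrt(rowSums(qm^2))
  out <- qm / n
  if (is.null(dim(q))) out[1L, ] else out
}

quat_conjugate <- function(q) {
  qm <- .as_qmat(q)
  out <- cbind(qm[, 1L], -qm[, 2L], -qm[, 3L], -qm[, 4L])
  if (is.null(dim(q))) out[1L, ] else out
}

#' Hamilton product of quaternions (rowwise)
#' @noRd
quat_multiply <- function(p, q) {
  pm <- .as_qmat(p); qm <- .as_qmat(q)
  if (nrow(pm) == 1L && nrow(qm) > 1L) pm <- pm[rep(1L, nrow(qm)), , drop = FALSE]
  if (nrow(qm) == 1L && nrow(pm) > 1L) qm <- qm[rep(1L, nrow(pm)), , drop = FALSE]
  w <- pm[, 1L] * qm[, 1L] - pm[, 2L] * qm[, 2L] - pm[, 3L] * qm[, 3L] - pm[, 4L] * qm[, 4L]
  x <- pm[, 1L] * qm[, 2L] + pm[, 2L] * qm[, 1L] + pm[, 3L] * qm[, 4L] - pm[, 4L] * qm[, 3L]
  y <- pm[, 1L] * qm[, 3L] - pm[, 2L] * qm[, 4L] + pm[, 3L] * qm[, 1L] + pm[, 4L] * qm[, 2L]
  z <- pm[, 1L] * qm[, 4L] + pm[, 2L] * qm[, 3L] - pm[, 3L] * qm[, 2L] + pm[, 4L] * qm[, 1L]
  out <- cbind(w, x, y, z)
  dimnames(out) <- NULL
  if (is.null(dim(p)) && is.null(dim(q))) out[1L, ] else out
}

.cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Rotate 3-vectors by unit quaternions (local -> global)
#'
#' @param q length-4 vector or n x 4 matrix of unit quaternions.
#' @param v length-3 vector or n x 3 matrix of vectors in the local frame.
#' @return Vectors expressed in the global frame, same shape as `v`.
#' @noRd
quat_rotate <- function(q, v) {
  qm <- .as_qmat(q)
  vm <- if (is.null(dim(v))) matrix(v, nrow = 1L) else as.matrix(v)
  if (nrow(qm) == 1L && nrow(vm) > 1L) qm <- qm[rep(1L, nrow(vm)), , drop = FALSE]
  if (nrow(vm) == 1L && nrow(qm) > 1L) vm <- vm[rep(1L, nrow(qm)), , drop = FALSE]
  qv <- qm[, 2:4, drop = FALSE]
  tt <- 2 * .cross3(qv, vm)
  out <- vm + qm[, 1L] * tt + .cross3(qv, tt)
  dimnames(out) <- NULL
  if (is.null(dim(v)) && is.null(dim(q))) out[1L, ] else out
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Shortest-arc rotation carrying unit vector u onto unit vector v
#' @noRd
quat_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  d <- sum(u * v)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # opposite vectors: pick any axis orthogonal to u
    axis <- c(1, 0, 0) - u * u[1L]
    if (sum(axis^2) < 1e-12) axis <- c(0, 1, 0) - u * u[2L]
    return(quat_from_axis_angle(axis, pi))
  }
  axis <- c(u[2L] * v[3L] - u[3L] * v[2L],
            u[3L] * v[1L] - u[1L] * v[3L],
            u[1L] * v[2L] - u[2L] * v[1L])
  quat_from_axis_angle(axis, acos(d))
}

#' Integrate body-frame angular velocity into an orientation track
#'
#' First-order quaternion integration of dq/dt = q * (0, omega)/2 where
#' omega is expressed in the (rotating) local frame.
#'
#' @param omega n x 3 matrix of angular velocity (rad/s, local frame).
#' @param fs sample rate (Hz).
#' @param q0 initial orientation (local -> global), default identity.
#' @return n x 4 matrix of unit quaternions.
#' @noRd
quat_integrate <- function(omega, fs, q0 = c(1, 0, 0, 0)) {
  omega <- as.matrix(omega)
  n <- nrow(omega)
  out <- matrix(0, n, 4L)
  qn0 <- sqrt(sum(q0^2))
  a <- q0[1L] / qn0; b <- q0[2L] / qn0; c <- q0[3L] / qn0; d <- q0[4L] / qn0
  h <- 0.5 / fs
  out[1L, ] <- c(a, b, c, d)
  if (n == 1L) return(out)
  for (i in 2:n) {
    wx <- omega[i - 1L, 1L]; wy <- omega[i - 1L, 2L]; wz <- omega[i - 1L, 3L]
    a1 <- a + h * (-b * wx - c * wy - d * wz)
    b1 <- b + h * (a * wx + c * wz - d * wy)
    c1 <- c + h * (a * wy - b * wz + d * wx)
    d1 <- d + h * (a * wz + b * wy - c * wx)
    nn <- sqrt(a1 * a1 + b1 * b1 + c1 * c1 + d1 * d1)
    a <- a1 / nn; b <- b1 / nn; c <- c1 / nn; d <- d1 / nn
    out[i, 1L] <- a; out[i, 2L] <- b; out[i, 3L] <- c; out[i, 4L] <- d
  }
  out
}

#' Angle (rad) between the gravity axes implied by two orientation tracks
#' @noRd
quat_tilt_error <- function(q_est, q_true) {
  zhat <- c(0, 0, 1)
  g_est <- quat_rotate(quat_conjugate(q_est), matrix(zhat, nrow(.as_qmat(q_est)), 3, byrow = TRUE))
  g_true <- quat_rotate(quat_conjugate(q_true), matrix(zhat, nrow(.as_qmat(q_true)), 3, byrow = TRUE))
  d <- pmin(pmax(rowSums(g_est * g_true), -1), 1)
  acos(d)
}
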