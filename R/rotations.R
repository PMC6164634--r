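# Minimal quaternion / rotation-matrix toolbox used by the orientation
# estimators and the synthetic IMU generator. Quaternions are scalar-first
# numeric(4), unit norm, q and -q encode the same rotation.

quat_normalize <- function(q) q / sqrt(sum(q * q))

quat_conj <- function(q) c(q[1], -q[2:4])

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - sum(p[2:4] * q[2:4]),
    p[1] * q[2:4] + q[1] * p[2:4] + pracma::cross(p[2:4], q[2:4]))
}

quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
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
  quat_normalize(q)
}

# Axis-angle rotation matrix (Rodrigues), axis any nonzero 3-vector.
rot_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Propagate a body-frame angular rate over dt (first-order exponential map).
quat_integrate <- function(q, omega, dt) {
  th <- sqrt(sum(omega^2)) * dt
  if (th < 1e-12) return(quat_normalize(q))
  axis <- omega / sqrt(sum(omega^2))
  dq <- c(cos(th / 2), sin(th / 2) * axis)
  quat_normalize(quat_multiply(q, dq))
}

# Normalized linear interpolation between quaternions (sign-aligned).
quat_nlerp <- function(p, q, alpha) {
  if (sum(p * q) < 0) q <- -q
  quat_normalize((1 - alpha) * p + alpha * q)
}

# ZYX (yaw-pitch-roll) Euler angles: R = Rz(psi) %*% Ry(theta) %*% Rx(phi).
euler_zyx_to_matrix <- function(phi, theta, psi) {
  rot_axis_angle(c(0, 0, 1), psi) %*%
    rot_axis_angle(c(0, 1, 0), theta) %*%
    rot_axis_angle(c(1, 0, 0), phi)
}

matrix_to_euler_zyx <- function(R) {
  theta <- asin(-min(max(R[3, 1], -1), 1))
  if (abs(R[3, 1]) < 1 - 1e-9) {
    phi <- atan2(R[3, 2], R[3, 3])
    psi <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock: split arbitrarily, keep roll
    phi <- atan2(-R[2, 3], R[2, 2])
    psi <- 0
  }
  c(phi = phi, theta = theta, psi = psi)
}

# vee of the skew-symmetric part of a 3x3 matrix.
skew_vee <- function(M) {
  S <- (M - t(M)) / 2
  c(S[3, 2], S[1, 3], S[2, 1])
}
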