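#' Least-squares joint speeds from stacked gyroscope readings
#'
#' Solves `omega_stack = J %*% speeds` in the least-squares sense through a
#' tolerance-regularized Moore-Penrose pseudo-inverse: singular values below
#' `tol * max(singular value)` are truncated and the result is flagged as
#' degenerate.
#'
#' @param jacobian 9x7 gyroscope Jacobian, see [arm_jacobian()].
#' @param omega_stack numeric 9-vector of stacked angular velocities (rad/s)
#'   from the upper-arm, wrist and hand IMUs.
#' @param tol relative singular-value truncation tolerance.
#' @return numeric 7-vector of joint speeds (rad/s) with attribute
#'   `degenerate` (logical: rank deficiency detected).
#' @export
estimate_joint_speeds <- function(jacobian, omega_stack, tol = 1e-8) {
  stopifnot_contract(is.matrix(jacobian) && all(dim(jacobian) == c(9, 7)),
                     "jacobian must be 9x7")
  stopifnot_contract(length(omega_stack) == 9 && all(is.finite(omega_stack)),
                     "omega_stack must be a finite 9-vector")
  sv <- svd(jacobian)
  keep <- sv$d > tol * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  speeds <- sv$v %*% (dinv * (t(sv$u) %*% omega_stack))
  structure(as.numeric(speeds), degenerate = any(!keep))
}

#' Integrate joint speeds into joint angles
#'
#' Trapezoidal integration of joint rotational speeds from a known initial
#' posture, with optional first-order drift correction: when a `reference`
#' series of absolute joint-angle observations is supplied (e.g. derived
#' from accelerometer/magnetometer orientation estimates), each step adds
#' `gain * wrap(reference - estimate)` to the speed before integrating.
#' With `gain = 0` this reduces to pure integration. Angles are wrapped to
#' `(-pi, pi]` after each step.
#'
#' @param speeds n x 7 matrix of joint speeds (rad/s).
#' @param t numeric n-vector of uniformly spaced timestamps (s).
#' @param initial numeric 7-vector, calibration posture (rad).
#' @param gain scalar or 7-vector error-correction gain (1/s), >= 0.
#' @param reference optional n x 7 matrix of absolute joint-angle
#'   observations used to form the per-step orientation-error vector; may
#'   also be passed as a precomputed n x 7 error stream via `error_stream`.
#' @param error_stream optional n x 7 matrix of per-step error vectors
#'   (used directly if `reference` is `NULL`).
#' @return n x 7 matrix of joint angles (rad), wrapped to `(-pi, pi]`.
#' @export
integrate_joint_angles <- function(speeds, t, initial, gain = 0,
                                   reference = NULL, error_stream = NULL) {
  speeds <- as.matrix(speeds)
  n <- nrow(speeds)
  stopifnot_contract(ncol(speeds) == 7, "speeds must have 7 columns")
  stopifnot_contract(length(t) == n, "t must match speeds rows")
  stopifnot_contract(length(initial) == 7 && all(is.finite(initial)),
                     "initial must be a finite 7-vector")
  stopifnot_contract(all(gain >= 0), "gain must be >= 0")
  dt <- check_uniform_dt(t)
  if (length(gain) == 1) gain <- rep(gain, 7)
  angles <- matrix(NA_real_, n, 7)
  angles[1, ] <- wrap_angle(initial)
  th <- angles[1, ]
  for (k in seq_len(n - 1)) {
    corr <- if (!is.null(reference)) {
      gain * wrap_angle(reference[k, ] - th)
    } else if (!is.null(error_stream)) {
      gain * error_stream[k, ]
    } else rep(0, 7)
    th <- th + dt * (0.5 * (speeds[k, ] + speeds[k + 1, ]) + corr)
    th <- wrap_angle(th)
    angles[k + 1, ] <- th
  }
  angles
}

#' Estimate arm joint angles from raw multi-IMU gyroscope streams
#'
#' Runs the full inverse sequence at stream level: at each sample the
#' gyroscope Jacobian is evaluated at the current angle estimate, joint
#' speeds are recovered through the pseudo-inverse, and angles are advanced
#' by Heun (trapezoidal predictor-corrector) integration, with optional
#' drift correction against absolute joint-angle observations.
#'
#' @param model an [arm_model()].
#' @param omega n x 9 matrix of stacked gyroscope readings (rad/s): columns
#'   1-3 upper-arm sensor, 4-6 wrist sensor, 7-9 hand sensor, each in its
#'   own sensor frame.
#' @param t uniformly spaced timestamps (s).
#' @param initial calibration posture, 7-vector (rad).
#' @param gain drift-correction gain (1/s); 0 disables correction.
#' @param reference optional n x 7 absolute joint-angle observations.
#' @param trunk_omega optional n x 3 matrix of trunk gyroscope readings.
#'   Arm-mounted gyros measure absolute angular velocity; all quantities are
#'   computed relative to the trunk, so when supplied the trunk rate
#'   (rotated into each sensor frame at the current posture estimate) is
#'   subtracted from the stacked readings before inversion.
#' @return list with `t`, `angles` (n x 7), `speeds` (n x 7) and
#'   `degenerate` (logical n-vector flagging rank-deficient samples).
#' @export
estimate_arm_motion <- function(model, omega, t, initial, gain = 0,
                                reference = NULL, trunk_omega = NULL) {
  omega <- as.matrix(omega)
  n <- nrow(omega)
  stopifnot_contract(ncol(omega) == 9, "omega must have 9 columns")
  stopifnot_contract(length(t) == n, "t must match omega rows")
  dt <- check_uniform_dt(t)
  if (length(gain) == 1) gain <- rep(gain, 7)
  angles <- matrix(NA_real_, n, 7)
  speeds <- matrix(NA_real_, n, 7)
  degen <- logical(n)
  rel_omega <- function(k, th_at) {
    om <- omega[k, ]
    if (!is.null(trunk_omega)) {
      chain <- fk_chain(model, th_at)
      wt <- trunk_omega[k, ]
      sj <- model$sensor_joints
      for (s in 1:3) {
        rows <- (3 * s - 2):(3 * s)
        om[rows] <- om[rows] - as.numeric(crossprod(chain[[sj[[s]]]]$R, wt))
      }
    }
    om
  }
  th <- wrap_angle(initial)
  angles[1, ] <- th
  v <- estimate_joint_speeds(arm_jacobian(model, th), rel_omega(1, th))
  degen[1] <- attr(v, "degenerate")
  speeds[1, ] <- v
  for (k in seq_len(n - 1)) {
    corr <- if (!is.null(reference)) gain * wrap_angle(reference[k, ] - th)
            else rep(0, 7)
    vk <- speeds[k, ]
    # Heun step: predict with the current speed, evaluate the Jacobian at
    # the prediction, correct with the speed average
    th_pred <- wrap_angle(th + dt * (vk + corr))
    v2 <- estimate_joint_speeds(arm_jacobian(model, th_pred),
                                rel_omega(k + 1, th_pred))
    degen[k + 1] <- attr(v2, "degenerate")
    th <- wrap_angle(th + dt * (0.5 * (vk + as.numeric(v2)) + corr))
    angles[k + 1, ] <- th
    speeds[k + 1, ] <- v2
  }
  list(t = t, angles = angles, speeds = speeds, degenerate = degen)
}

#' Absolute orientation from gravity and magnetic field (q-method)
#'
#' Closed-form solution of the Wahba problem for two vector observations:
#' finds the rotation `A` minimizing the weighted misfit between measured
#' body-frame vectors and reference vectors, i.e. `accel ~ A %*% ref_gravity`
#' and `mag ~ A %*% ref_field`. The optimum is the principal eigenvector of
#' Davenport's K matrix.
#'
#' @param accel measured acceleration direction (body frame), 3-vector.
#' @param mag measured magnetic field direction (body frame), 3-vector.
#' @param ref_gravity,ref_field the same two directions in the reference
#'   frame.
#' @param weights length-2 observation weights (gravity, field).
#' @return unit quaternion (scalar first) of the body-from-reference
#'   rotation: `quat_to_matrix(q) %*% ref` reproduces the measurement.
#' @export
estimate_orientation_from_field <- function(accel, mag,
                                            ref_gravity = c(0, 0, 1),
                                            ref_field = c(0.5, 0, -sqrt(3)/2),
                                            weights = c(0.5, 0.5)) {
  unit <- function(v) {
    v <- as.numeric(v)
    nv <- sqrt(sum(v^2))
    stopifnot_contract(nv > 0, "observation vectors must be nonzero")
    v / nv
  }
  b <- list(unit(accel), unit(mag))
  r <- list(unit(ref_gravity), unit(ref_field))
  cr <- pracma::cross(b[[1]], b[[2]])
  if (sqrt(sum(cr^2)) < 1e-8) {
    abort_aq("araquant_error_degenerate",
             "acceleration and field observations are (anti)parallel")
  }
  B <- weights[1] * (b[[1]] %o% r[[1]]) + weights[2] * (b[[2]] %o% r[[2]])
  sigma <- sum(diag(B))
  z <- c(B[2, 3] - B[3, 2], B[3, 1] - B[1, 3], B[1, 2] - B[2, 1])
  K <- rbind(c(sigma, -z), cbind(-z, B + t(B) - sigma * diag(3)))
  eg <- eigen(K, symmetric = TRUE)
  q <- eg$vectors[, 1]
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Trunk orientation angles from the sternum IMU stream
#'
#' Gyroscope propagation fused with field-based absolute orientation in a
#' complementary structure: each step blends the gyro-propagated quaternion
#' toward the q-method estimate from accelerometer and magnetometer. The
#' stream must start with a quasi-static calibration window (gyro magnitude
#' below `static_thresh` for at least `calib_s` seconds); the mean absolute
#' orientation over that window defines the reference, and the returned
#' angles are the ZYX Euler deviations (phi roll, theta pitch, psi yaw) of
#' the trunk from that reference.
#'
#' @param stream data frame with columns `t, gx, gy, gz, ax, ay, az,
#'   mx, my, mz` for the trunk sensor.
#' @param field_weight complementary blend weight toward the absolute
#'   orientation per step (gyro weight is `1 - field_weight`).
#' @param ref_gravity,ref_field reference directions, see
#'   [estimate_orientation_from_field()].
#' @param static_thresh gyro magnitude threshold (rad/s) for the static
#'   calibration detector.
#' @param calib_s minimum calibration window length (s).
#' @return data frame `t, phi, theta, psi` (radians, wrapped).
#' @export
estimate_trunk_angles <- function(stream, field_weight = 0.02,
                                  ref_gravity = c(0, 0, 1),
                                  ref_field = c(0.5, 0, -sqrt(3)/2),
                                  static_thresh = 0.05, calib_s = 1.0) {
  t <- stream$t
  n <- length(t)
  dt <- check_uniform_dt(t)
  gyro <- as.matrix(stream[, c("gx", "gy", "gz")])
  acc <- as.matrix(stream[, c("ax", "ay", "az")])
  mag <- as.matrix(stream[, c("mx", "my", "mz")])
  gmag <- row_norms(gyro)
  n_cal <- ceiling(calib_s / dt)
  if (n < n_cal || any(gmag[1:n_cal] > static_thresh)) {
    abort_aq("araquant_error_calibration",
             "no quasi-static calibration window at stream start")
  }
  obs_q <- function(k) estimate_orientation_from_field(
    acc[k, ], mag[k, ], ref_gravity, ref_field)
  # reference orientation: sign-aligned mean quaternion over the window
  q0 <- obs_q(1)
  qsum <- q0
  for (k in 2:n_cal) {
    qk <- obs_q(k)
    if (sum(qk * q0) < 0) qk <- -qk
    qsum <- qsum + qk
  }
  # switch to the attitude (world-from-body) convention for propagation:
  # attitude_dot = attitude * skew(omega_body), i.e. right-multiplication,
  # which is what quat_integrate implements
  q_ref <- quat_conj(quat_normalize(qsum))
  R_ref <- quat_to_matrix(q_ref)
  q <- q_ref
  out <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    if (k > 1) {
      q <- quat_integrate(q, gyro[k - 1, ], dt)
      q <- quat_nlerp(q, quat_conj(obs_q(k)), field_weight)
    }
    # deviation of the current trunk attitude from the calibration attitude,
    # expressed in the calibration frame
    R_dev <- t(R_ref) %*% quat_to_matrix(q)
    out[k, ] <- matrix_to_euler_zyx(R_dev)
  }
  data.frame(t = t, phi = wrap_angle(out[, 1]), theta = wrap_angle(out[, 2]),
             psi = wrap_angle(out[, 3]))
}
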