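#' Seven degree-of-freedom arm model
#'
#' Builds the kinematic chain used throughout the package. Joints are
#' ordered proximal to distal: (1) shoulder flexion(-)/extension(+),
#' (2) shoulder abduction(-)/adduction(+), (3) shoulder internal(-)/
#' external(+) rotation, (4) elbow flexion(+)/extension(-), (5) wrist
#' pronation(-)/supination(+), (6) wrist ulnar(-)/radial(+) deviation,
#' (7) wrist flexion(+)/extension(-).
#'
#' The trunk frame is right-handed with x pointing forward, y to the
#' subject's left and z up. With all joint angles at zero the arm hangs
#' along the trunk axis, so the hand sits at
#' \code{(0, 0, -(upper_arm + forearm + hand))} — the reference posture of
#' the calibration stance. Each link is realized as a rotation about a fixed
#' local axis followed by a translation along the segment; the concrete
#' axis/offset assignment is stored in \code{dh_table} and locked by the
#' zero-posture unit test. Three IMU frames ride on the chain: upper arm
#' (after joint 3), wrist (after joint 5) and hand (after joint 7).
#'
#' @param handedness `"right"` or `"left"`. The chain is identical for both
#'   arms; handedness is carried as metadata and used when mirroring
#'   trajectories for comparison against a right-arm reference.
#' @param upper_arm_m,forearm_m,hand_m segment lengths in meters.
#' @return an object of class `arm_model`.
#' @examples
#' m <- arm_model()
#' forward_kinematics(m, rep(0, 7))$position
#' @export
arm_model <- function(handedness = c("right", "left"),
                      upper_arm_m = 0.30, forearm_m = 0.26, hand_m = 0.08) {
  handedness <- match.arg(handedness)
  stopifnot_contract(upper_arm_m > 0 && forearm_m > 0 && hand_m > 0,
                     "segment lengths must be positive")
  # axis: joint rotation axis in its local (pre-rotation) frame
  # offset: translation applied after the rotation, in the rotated frame
  dh_table <- list(
    list(axis = c(0,  1, 0), offset = c(0, 0, 0)),              # shoulder F/E
    list(axis = c(1,  0, 0), offset = c(0, 0, 0)),              # shoulder Ab/Ad
    list(axis = c(0,  0, 1), offset = c(0, 0, -upper_arm_m)),   # shoulder rot
    list(axis = c(0, -1, 0), offset = c(0, 0, 0)),              # elbow F/E
    list(axis = c(0,  0, 1), offset = c(0, 0, -forearm_m)),     # pron/sup
    list(axis = c(1,  0, 0), offset = c(0, 0, 0)),              # ulnar/radial
    list(axis = c(0, -1, 0), offset = c(0, 0, -hand_m))         # wrist F/E
  )
  structure(list(
    handedness = handedness,
    segment_lengths = c(upper_arm = upper_arm_m, forearm = forearm_m,
                        hand = hand_m),
    joint_names = c("shoulder_flex_ext", "shoulder_abd_add",
                    "shoulder_int_ext_rot", "elbow_flex_ext",
                    "wrist_pron_sup", "wrist_ulnar_radial",
                    "wrist_flex_ext"),
    sensor_joints = c(upper = 3L, wrist = 5L, hand = 7L),
    dh_table = dh_table
  ), class = "arm_model")
}

check_angles7 <- function(angles) {
  stopifnot_contract(is.numeric(angles) && length(angles) == 7 &&
                       all(is.finite(angles)),
                     "angles must be a finite numeric 7-vector")
}

# Full chain evaluation: rotation matrix and origin of the frame after each
# joint (translation included). Internal workhorse for forward kinematics,
# the Jacobian and the synthetic IMU generator.
fk_chain <- function(model, angles) {
  check_angles7(angles)
  R <- diag(3)
  p <- c(0, 0, 0)
  out <- vector("list", 7L)
  for (j in 1:7) {
    link <- model$dh_table[[j]]
    R <- R %*% rot_axis_angle(link$axis, angles[j])
    p <- p + R %*% link$offset
    out[[j]] <- list(R = R, p = as.numeric(p))
  }
  out
}

#' Forward kinematics: hand pose in the trunk frame
#'
#' Composes the seven link transforms into the homogeneous transform of the
#' hand frame expressed in the trunk frame.
#'
#' @param model an [arm_model()].
#' @param angles numeric 7-vector of joint angles (rad).
#' @return a list with `transform` (4x4 homogeneous matrix), `rotation`
#'   (3x3), and `position` (3-vector, meters).
#' @export
forward_kinematics <- function(model, angles) {
  chain <- fk_chain(model, angles)
  hand <- chain[[7]]
  T <- diag(4)
  T[1:3, 1:3] <- hand$R
  T[1:3, 4] <- hand$p
  list(transform = T, rotation = hand$R, position = hand$p)
}

#' Gyroscope Jacobian of the arm chain
#'
#' Returns the 9x7 matrix mapping joint rotational speeds to the stacked
#' angular velocities of the three arm-mounted IMUs (upper arm, wrist,
#' hand), each expressed in its own sensor frame. Rows 1-3 belong to the
#' upper-arm sensor, 4-6 to the wrist sensor, 7-9 to the hand sensor.
#'
#' @inheritParams forward_kinematics
#' @return 9x7 numeric matrix.
#' @export
arm_jacobian <- function(model, angles) {
  check_angles7(angles)
  # world-frame joint axes: axis j lives in the frame after joints 1..j-1
  axes_w <- matrix(0, 3, 7)
  R_after <- vector("list", 7L)
  R <- diag(3)
  for (j in 1:7) {
    axes_w[, j] <- R %*% model$dh_table[[j]]$axis
    R <- R %*% rot_axis_angle(model$dh_table[[j]]$axis, angles[j])
    R_after[[j]] <- R
  }
  J <- matrix(0, nrow = 9, ncol = 7)
  sensors <- model$sensor_joints
  for (s in seq_along(sensors)) {
    k <- sensors[[s]]
    rows <- (3 * (s - 1) + 1):(3 * s)
    # world-frame axes of joints 1..k, expressed in sensor-s body frame
    J[rows, 1:k] <- crossprod(R_after[[k]], axes_w[, 1:k, drop = FALSE])
  }
  J
}
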