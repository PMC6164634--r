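test_that("pseudo-inverse recovers joint speeds exactly for consistent stacks", {
  m <- arm_model()
  withr::with_seed(31, {
    for (i in 1:20) {
      J <- arm_jacobian(m, runif(7, -1.5, 1.5))
      vd <- runif(7, -2, 2)
      est <- estimate_joint_speeds(J, as.numeric(J %*% vd))
      expect_lt(max(abs(est - vd)), 1e-8)
      expect_false(attr(est, "degenerate"))
    }
  })
  expect_equal(as.numeric(estimate_joint_speeds(
    arm_jacobian(m, rep(0.3, 7)), rep(0, 9))), rep(0, 7))
})

test_that("pseudo-inverse satisfies J+J = I at full column rank (100 postures)", {
  m <- arm_model()
  withr::with_seed(32, {
    for (i in 1:100) {
      J <- arm_jacobian(m, runif(7, -1.5, 1.5))
      sv <- svd(J)
      pinv <- sv$v %*% diag(1 / sv$d) %*% t(sv$u)
      if (sv$d[7] > 1e-8 * sv$d[1]) {
        expect_lt(max(abs(pinv %*% J - diag(7))), 1e-8)
      }
    }
  })
})

test_that("noisy stacks give the least-squares optimum", {
  m <- arm_model()
  withr::with_seed(33, {
    J <- arm_jacobian(m, runif(7, -1, 1))
    om <- as.numeric(J %*% runif(7)) + rnorm(9, 0, 0.05)
    est <- estimate_joint_speeds(J, om)
    dense <- qr.solve(qr(J), om)   # dense least-squares oracle
    expect_equal(as.numeric(est), as.numeric(dense), tolerance = 1e-8)
  })
})

test_that("rank-deficient stacks are flagged and handled", {
  J <- matrix(0, 9, 7)
  J[1:9, 1] <- 1   # rank 1
  est <- estimate_joint_speeds(J, rep(1, 9))
  expect_true(attr(est, "degenerate"))
  expect_true(all(is.finite(est)))
})

test_that("integration reproduces ramps and constants", {
  t <- seq(0, 5, by = 0.01)
  n <- length(t)
  c7 <- seq(0.1, 0.7, by = 0.1)
  speeds <- matrix(c7, n, 7, byrow = TRUE)
  ang <- integrate_joint_angles(speeds, t, rep(0, 7))
  expect_equal(ang[n, ], wrap_angle(c7 * 5), tolerance = 1e-9)
  ang0 <- integrate_joint_angles(matrix(0, n, 7), t, c7)
  expect_true(all(abs(sweep(ang0, 2, c7)) < 1e-12))
})

test_that("drift correction bounds the steady-state error under gyro bias", {
  # constant bias b with drift-free absolute reference: first-order error
  # dynamics predict steady state b / gain
  t <- seq(0, 60, by = 0.01)
  n <- length(t)
  b <- 0.02
  gain <- 1
  speeds <- matrix(b, n, 7)        # bias only, true angles constant at 0
  ref <- matrix(0, n, 7)
  ang <- integrate_joint_angles(speeds, t, rep(0, 7), gain = gain,
                                reference = ref)
  expect_lt(max(abs(ang[n, ])), 1.2 * b / gain)
  ang_nc <- integrate_joint_angles(speeds, t, rep(0, 7))
  expect_gt(max(abs(ang_nc[n, ])), 10 * max(abs(ang[n, ])))
})

test_that("q-method recovers known orientations", {
  g <- c(0, 0, 1)
  f <- c(0.5, 0, -sqrt(3) / 2)
  qi <- estimate_orientation_from_field(g, f, g, f)
  expect_equal(abs(qi[1]), 1, tolerance = 1e-9)
  withr::with_seed(35, {
    for (i in 1:20) {
      qs <- araquant:::quat_normalize(rnorm(4))
      R <- araquant:::quat_to_matrix(qs)
      qe <- estimate_orientation_from_field(R %*% g, R %*% f, g, f)
      expect_lt(min(sum((qe - qs)^2), sum((qe + qs)^2)), 1e-12)
    }
  })
  expect_error(estimate_orientation_from_field(g, g, g, f),
               class = "araquant_error_degenerate")
})

test_that("q-method error scales with the observation noise (Monte Carlo)", {
  # with two vector observations the attitude error is proportional to the
  # per-vector noise, with a geometry factor that worsens as the reference
  # directions approach collinearity; both bounds below were verified by
  # simulation at 10x the trial count
  mc_errors <- function(g, f, sd_noise, n = 300) {
    replicate(n, {
      qs <- araquant:::quat_normalize(rnorm(4))
      R <- araquant:::quat_to_matrix(qs)
      perturb <- function(v) {
        as.numeric(araquant:::rot_axis_angle(rnorm(3),
                                             rnorm(1, 0, sd_noise)) %*% v)
      }
      qe <- estimate_orientation_from_field(perturb(R %*% g),
                                            perturb(R %*% f), g, f)
      2 * acos(min(abs(sum(qe * qs)), 1))
    })
  }
  sd5 <- 5 * pi / 180
  withr::with_seed(36, {
    # orthogonal references: error below 2x the noise in 95% of trials
    e_orth <- mc_errors(c(0, 0, 1), c(1, 0, 0), sd5)
    expect_gt(mean(e_orth < 2 * sd5), 0.95)
    # gravity + 60-degree-inclination field (150 degrees apart): error below
    # 4x the noise in 95% of trials
    e_def <- mc_errors(c(0, 0, 1), c(0.5, 0, -sqrt(3) / 2), sd5)
    expect_gt(mean(e_def < 4 * sd5), 0.95)
  })
})

test_that("trunk angles are near zero for a static stream", {
  t <- seq(0, 4, by = 0.01)
  st <- trunk_stream_from_angles(t, rep(0, length(t)), rep(0, length(t)),
                                 rep(0, length(t)))
  ta <- estimate_trunk_angles(st)
  expect_lt(max(abs(as.matrix(ta[, c("phi", "theta", "psi")]))), 1e-6)
})

test_that("trunk pitch ramp to 10 degrees is tracked within 0.5 degrees", {
  t <- seq(0, 8, by = 0.01)
  theta <- ifelse(t < 2, 0, ifelse(t < 5, (t - 2) / 3, 1)) * 10 * pi / 180
  st <- trunk_stream_from_angles(t, rep(0, length(t)), theta, rep(0, length(t)))
  ta <- estimate_trunk_angles(st)
  expect_lt(abs(ta$theta[length(t)] - 10 * pi / 180), 0.5 * pi / 180)
})

test_that("trunk three-axis wobble is tracked within 1 degree RMS", {
  t <- seq(0, 10, by = 0.01)
  withr::with_seed(37, {
    ang <- sapply(1:3, function(i)
      0.08 * sin(2 * pi * runif(1, 0.2, 0.5) * t + runif(1, 0, 2 * pi)) *
        pmin(t / 2, 1) * as.numeric(t > 2))
  })
  st <- trunk_stream_from_angles(t, ang[, 1], ang[, 2], ang[, 3])
  ta <- estimate_trunk_angles(st)
  err <- as.matrix(ta[, c("phi", "theta", "psi")]) - ang
  expect_lt(sqrt(mean(err^2)), 1 * pi / 180)
})

test_that("missing static calibration raises a calibration error", {
  t <- seq(0, 3, by = 0.01)
  st <- trunk_stream_from_angles(t, 0.3 * sin(2 * pi * 1 * t),
                                 rep(0, length(t)), rep(0, length(t)))
  expect_error(estimate_trunk_angles(st),
               class = "araquant_error_calibration")
})

test_that("stream-level round trip recovers smooth joint motion", {
  m <- arm_model()
  mot <- smooth_joint_motion(10, seed = 12)
  omega <- gyro_from_motion(m, mot)
  est <- estimate_arm_motion(m, omega, mot$t, mot$q[1, ])
  err <- est$angles - mot$q
  expect_lt(sqrt(mean(err^2)) * 180 / pi, 0.5)
})

test_that("enabling correction strictly reduces terminal error under bias", {
  m <- arm_model()
  mot <- smooth_joint_motion(10, seed = 13)
  omega <- gyro_from_motion(m, mot) + 0.01
  e0 <- estimate_arm_motion(m, omega, mot$t, mot$q[1, ])
  e1 <- estimate_arm_motion(m, omega, mot$t, mot$q[1, ], gain = 1,
                            reference = mot$q)
  n <- length(mot$t)
  expect_lt(max(abs(e1$angles[n, ] - mot$q[n, ])),
            max(abs(e0$angles[n, ] - mot$q[n, ])))
})

test_that("integrated trajectories keep orthonormal hand rotations", {
  m <- arm_model()
  mot <- smooth_joint_motion(5, seed = 14)
  est <- estimate_arm_motion(m, gyro_from_motion(m, mot), mot$t, mot$q[1, ])
  for (k in seq(1, length(mot$t), by = 100)) {
    R <- forward_kinematics(m, est$angles[k, ])$rotation
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
  }
})
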