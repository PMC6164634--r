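# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: rotations are built from explicit axis
# matrices, derivatives from central differences, p-values from brute-force
# enumeration.

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

# rotation about a signed unit axis (+-x, +-y, +-z only)
rot_unit_axis <- function(axis, angle) {
  i <- which(axis != 0)
  a <- angle * sign(axis[i])
  switch(i, rot_x(a), rot_y(a), rot_z(a))
}

# brute-force forward kinematics: explicit 4x4 homogeneous matrix products
# straight off the model's link table
oracle_fk <- function(model, angles, upto = 7) {
  T <- diag(4)
  for (j in seq_len(upto)) {
    link <- model$dh_table[[j]]
    R4 <- diag(4)
    R4[1:3, 1:3] <- rot_unit_axis(link$axis, angles[j])
    D4 <- diag(4)
    D4[1:3, 4] <- link$offset
    T <- T %*% R4 %*% D4
  }
  T
}

# finite-difference gyroscope Jacobian: omega_body = vee(R^T dR/dtheta_j)
oracle_jacobian <- function(model, angles, h = 1e-7) {
  vee <- function(S) c(S[3, 2], S[1, 3], S[2, 1])
  J <- matrix(0, 9, 7)
  for (j in 1:7) {
    qp <- angles; qm <- angles
    qp[j] <- qp[j] + h
    qm[j] <- qm[j] - h
    for (s in 1:3) {
      k <- model$sensor_joints[[s]]
      Rp <- oracle_fk(model, qp, k)[1:3, 1:3]
      Rm <- oracle_fk(model, qm, k)[1:3, 1:3]
      R0 <- oracle_fk(model, angles, k)[1:3, 1:3]
      S <- t(R0) %*% ((Rp - Rm) / (2 * h))
      J[(3 * s - 2):(3 * s), j] <- vee((S - t(S)) / 2)
    }
  }
  J
}

# exhaustive permutation oracle for the two-sided Mann-Whitney p-value,
# built on the U statistic from pairwise comparisons (not rank sums)
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  n <- length(y)
  u_stat <- function(a, b) {
    sum(outer(a, b, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  u_obs <- u_stat(x, y)
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  tol <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + tol), mean(us >= u_obs - tol)))
}

# explicit average-rank Spearman coefficient
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# smooth multi-sinusoid 7-joint trajectory with analytic speeds
smooth_joint_motion <- function(duration, fs = 100, seed = 11) {
  withr::with_seed(seed, {
    t <- seq(0, duration, by = 1 / fs)
    A <- runif(7, 0.2, 0.5)
    f <- runif(7, 0.1, 0.3)
    ph <- runif(7, 0, 2 * pi)
    q0 <- c(-0.3, 0, 0, 0.8, 0, 0, 0)
    q <- sapply(1:7, function(j)
      q0[j] + A[j] * (sin(2 * pi * f[j] * t + ph[j]) - sin(ph[j])))
    qd <- sapply(1:7, function(j)
      A[j] * 2 * pi * f[j] * cos(2 * pi * f[j] * t + ph[j]))
    list(t = t, q = q, qd = qd)
  })
}

# gyro streams synthesized through the Jacobian for a joint trajectory
gyro_from_motion <- function(model, mot) {
  t(vapply(seq_along(mot$t), function(k)
    as.numeric(arm_jacobian(model, mot$q[k, ]) %*% mot$qd[k, ]),
    numeric(9)))
}

# minimal arc_trajectory fixture with prescribed fields (for metric oracles)
make_arc <- function(position, nu = NULL, sbar = NULL, speed = NULL) {
  n <- nrow(position)
  if (is.null(sbar)) sbar <- seq(0, 1, length.out = n)
  structure(list(
    sbar = sbar, position = position,
    distance = sqrt(rowSums(sweep(position, 2, position[1, ])^2)),
    speed = if (is.null(speed)) rep(1, n) else speed,
    nu = if (is.null(nu)) rep(0, n) else nu,
    L = sum(sqrt(rowSums(diff(position)^2))),
    time_map = NULL, source = NULL
  ), class = "arc_trajectory")
}

make_ref <- function(position, sbar = NULL) {
  n <- nrow(position)
  if (is.null(sbar)) sbar <- seq(0, 1, length.out = n)
  structure(list(sbar = sbar, position = position,
                 iqr = matrix(0, n, 3)),
            class = "reference_trajectory")
}

# synthetic trunk IMU stream following a prescribed angle profile
trunk_stream_from_angles <- function(t, phi, theta, psi) {
  n <- length(t)
  quats <- matrix(NA_real_, n, 4)
  for (k in seq_len(n)) {
    quats[k, ] <- araquant:::quat_from_matrix(
      araquant:::euler_zyx_to_matrix(phi[k], theta[k], psi[k]))
    if (k > 1 && sum(quats[k, ] * quats[k - 1, ]) < 0)

      quats[k, ] <- -quats[k, ]
  }
  w <- araquant:::body_rates_from_quat(quats, t[2] - t[1])
  g_up <- c(0, 0, 9.81)
  m_ref <- c(0.5, 0, -sqrt(3) / 2)
  acc <- t(vapply(seq_len(n), function(k)
    as.numeric(crossprod(araquant:::quat_to_matrix(quats[k, ]), g_up)),
    numeric(3)))
  mag <- t(vapply(seq_len(n), function(k)
    as.numeric(crossprod(araquant:::quat_to_matrix(quats[k, ]), m_ref)),
    numeric(3)))
  data.frame(t = t, gx = w[, 1], gy = w[, 2], gz = w[, 3],
             ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
             mx = mag[, 1], my = mag[, 2], mz = mag[, 3])
}
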