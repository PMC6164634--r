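test_that("movement time is termination minus onset, per phase and task", {
  seg <- list(
    phases = data.frame(index = c(NA, 1, NA, 2, NA, 3, NA),
                        kind = c("hold", "reach_to_grasp", "grasp",
                                 "transfer", "release", "return", "hold"),
                        sbar_onset = 0, sbar_term = 1,
                        t_onset = c(0, 1.0, 2.5, 3.0, 4.2, 4.6, 8.0),
                        t_term = c(1, 2.5, 3.0, 4.2, 4.6, 8.0, 9.0),
                        auto = TRUE),
    movement_phase_indices = c(2L, 4L, 6L)
  )
  tm <- movement_time(seg)
  expect_equal(tm$T_m[tm$phase == "1"], 1.5)
  # task time spans first onset to last termination, dwells included
  expect_equal(tm$T_m[tm$phase == "task"], 7.0)
})

test_that("constant angular velocity yields the undefined-smoothness sentinel", {
  t <- seq(0, 2, by = 0.01)
  omega <- matrix(0.3, length(t), 3)
  eta <- rotational_jerk_index(omega, t, 0.2, 1.8)
  expect_identical(as.numeric(eta), -Inf)
  expect_true(attr(eta, "undefined_smoothness"))
})

minjerk_rotation <- function(T, fs = 100, amp = 1) {
  t <- seq(0, T, by = 1 / fs)
  tau <- t / T
  # bell-shaped angular-velocity profile completing `amp` radians
  omega <- amp * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / T
  list(t = t, omega = cbind(omega, 0, 0))
}

test_that("log dimensionless jerk is invariant to pure time scaling", {
  # same rotation at half duration: T^5 shrinks 32-fold while the squared
  # second derivative integral grows 32-fold, so the index is unchanged
  r1 <- minjerk_rotation(2.0, fs = 200)
  r2 <- minjerk_rotation(1.0, fs = 200)
  e1 <- rotational_jerk_index(r1$omega, r1$t, 0, 2.0, cutoff_hz = 0)
  e2 <- rotational_jerk_index(r2$omega, r2$t, 0, 1.0, cutoff_hz = 0)
  expect_equal(e1, e2, tolerance = 0.02)
})

test_that("tremor strictly increases the rotational jerk index", {
  withr::with_seed(51, {
    for (i in 1:30) {
      r <- minjerk_rotation(1.5)
      f <- runif(1, 4, 8)
      tremor <- 0.05 * max(abs(r$omega[, 1])) * sin(2 * pi * f * r$t +
                                                      runif(1, 0, 2 * pi))
      e0 <- rotational_jerk_index(r$omega, r$t, 0, 1.5)
      e1 <- rotational_jerk_index(r$omega + cbind(tremor, 0, 0), r$t, 0, 1.5)
      expect_gt(e1, e0)
    }
  })
})

test_that("reference trajectory is the coordinate-wise (lower) median", {
  n <- 11
  base <- cbind(seq(0, 1, length.out = n), 0, 0)
  a1 <- make_arc(base)
  a2 <- make_arc(base + 0.001)
  a3 <- make_arc(base + 1)   # outlier
  ref <- build_reference(list(a1, a2, a3))
  # tracks the two concordant trajectories pointwise
  expect_lt(max(abs(ref$position - (base + 0.001))), 1e-12)
  # identical copies reproduce any copy
  ref2 <- build_reference(list(a1, a1, a1))
  expect_equal(ref2$position, a1$position)
  # even count: lower-median convention
  ref4 <- build_reference(list(a1, a2, a3, make_arc(base + 2)))
  expect_lt(max(abs(ref4$position - (base + 0.001))), 1e-12)
  expect_error(build_reference(list(a1, a2)),
               class = "araquant_error_contract")
})

test_that("RMS Euclidean distance matches closed forms and quadrature", {
  n <- 201
  base <- cbind(seq(0, 1, length.out = n), 0, 0)
  arc <- make_arc(base)
  ref <- make_ref(base)
  expect_equal(euclidean_similarity(arc, ref), 0)
  # constant offset of norm 0.03
  off <- c(0.03, 0, 0) / sqrt(1)
  arc2 <- make_arc(sweep(base, 2, -off))
  expect_equal(euclidean_similarity(arc2, ref), 0.03, tolerance = 1e-12)
  # random smooth perturbation vs direct trapezoidal oracle
  withr::with_seed(52, {
    s <- seq(0, 1, length.out = n)
    pert <- cbind(0.01 * sin(2 * pi * s), 0.02 * cos(3 * pi * s), 0)
    arc3 <- make_arc(base + pert)
    d2 <- rowSums(pert^2)
    want <- sqrt(pracma::trapz(s[51:151], d2[51:151]) / (s[151] - s[51]))
    got <- euclidean_similarity(arc3, ref, s[51], s[151])
    expect_equal(got, want, tolerance = 1e-9)
  })
})

test_that("normalized direction-change RMS matches analytic values", {
  n <- 201
  base <- cbind(seq(0, 1, length.out = n), 0, 0)
  expect_equal(direction_change_rms(make_arc(base)), 0)
  arc <- make_arc(base, nu = rep(pi / 2, n))
  expect_equal(direction_change_rms(arc), 0.5, tolerance = 1e-12)
  # arbitrary profile vs quadrature oracle
  s <- seq(0, 1, length.out = n)
  nu <- 0.3 + 0.2 * sin(2 * pi * s)
  arc2 <- make_arc(base, nu = nu)
  want <- sqrt(pracma::trapz(s, nu^2) / 1) / pi
  expect_equal(direction_change_rms(arc2), want, tolerance = 1e-9)
  expect_true(direction_change_rms(arc2) >= 0 &&
                direction_change_rms(arc2) <= 1)
})

test_that("trajectory similarity combines its components linearly with the stated weights", {
  expect_equal(trajectory_similarity(0, 0), 0)
  expect_equal(trajectory_similarity(0.04, 0.2), 0.12)
  w <- similarity_weights(0.7, 0.3)
  expect_equal(trajectory_similarity(0.1, 0.5, w), 0.7 * 0.1 + 0.3 * 0.5)
  # linear in each argument
  expect_equal(trajectory_similarity(0.2, 0.1) - trajectory_similarity(0.1, 0.1),
               trajectory_similarity(0.1, 0) - trajectory_similarity(0, 0))
  # exact decomposition
  D <- 0.0321; nu <- 0.173
  expect_identical(trajectory_similarity(D, nu), 0.5 * D + 0.5 * nu)
})

test_that("trunk stability index equals analytic maxima", {
  t <- seq(0, 5, by = 0.01)
  still <- data.frame(t = t, phi = 0, theta = 0, psi = 0)
  expect_equal(trunk_stability_index(still, 0, 5), 0)
  # single-axis ramp to 10 degrees
  ramp <- data.frame(t = t, phi = 0, theta = pmin(t / 4, 1) * 0.174533,
                     psi = 0)
  expect_equal(trunk_stability_index(ramp, 0, 5), 0.174533,
               tolerance = 1e-9)
  # simultaneous 3/4-degree two-axis deviation: Pythagorean 5 degrees
  two <- data.frame(t = t, phi = pmin(t / 4, 1) * 3 * pi / 180,
                    theta = pmin(t / 4, 1) * 4 * pi / 180, psi = 0)
  expect_equal(trunk_stability_index(two, 0, 5), 5 * pi / 180,
               tolerance = 1e-9)
  # analytic maximum for any piecewise-linear single-axis profile
  tri <- data.frame(t = t, phi = 0, psi = 0,
                    theta = 0.2 * pmin(t, 5 - t) / 2.5)
  expect_equal(trunk_stability_index(tri, 0, 5), 0.2, tolerance = 1e-9)
})

test_that("phase EMG intensity matches closed forms and quadrature", {
  t <- seq(0, 2, by = 1 / 200)
  zero <- data.frame(t = t, matrix(0, length(t), 8))
  names(zero) <- c("t", paste0("e", 1:8))
  expect_equal(emg_rms(zero, 0, 2), 0)
  cst <- zero
  cst[paste0("e", 1:8)] <- 0.37
  expect_equal(emg_rms(cst, 0, 2), 2 * sqrt(2) * 0.37, tolerance = 1e-12)
  withr::with_seed(53, {
    noisy <- zero
    for (ch in paste0("e", 1:8)) {
      noisy[[ch]] <- sin(2 * pi * runif(1, 3, 9) * t + runif(1, 0, 2 * pi))
    }
    idx <- which(t >= 0.25 & t <= 1.75)
    ssq <- rowSums(as.matrix(noisy[idx, paste0("e", 1:8)])^2)
    want <- unname(sqrt(pracma::trapz(t[idx], ssq) /
                          (t[idx[length(idx)]] - t[idx[1]])))
    expect_equal(emg_rms(noisy, 0.25, 1.75), want, tolerance = 1e-9)
  })
  bad <- zero[, 1:8]
  expect_error(emg_rms(bad, 0, 2), class = "araquant_error_contract")
})

test_that("EMG normalization is a guarded ratio", {
  expect_equal(emg_normalize(0.5, 0.5), 1)
  expect_equal(emg_normalize(0, 0.5), 0)
  expect_error(emg_normalize(0.5, 0), class = "araquant_error_contract")
  expect_warning(r <- emg_normalize(0.6, 0.5), "submaximal")
  expect_true(attr(r, "submaximal_reference"))
})

test_that("synthetic grasp bursts normalize to the configured effort fraction", {
  rec <- generate_task(task_spec("grasp", 0.1), impairment_profile("H"),
                       seed = 3, streams = "emg")
  emg <- rec$streams$emg
  task <- emg[emg$segment == "task", ]
  mx <- emg[emg$segment == "max_effort", ]
  w_max <- emg_rms(mx, min(mx$t), max(mx$t))
  tb <- rec$truth$phases
  w <- emg_rms(task, tb$t_onset[2], tb$t_term[2])
  expect_equal(as.numeric(emg_normalize(w, w_max)), rec$truth$grasp_force,
               tolerance = 0.05)
})

test_that("path metrics do not depend on the time course of the movement", {
  rec <- generate_task(task_spec("grasp", 0.05), impairment_profile("H"),
                       seed = 6, streams = FALSE)
  tr1 <- time_trajectory(rec$truth$t, rec$truth$hand_position)
  tr2 <- time_trajectory(rec$truth$t * 3, rec$truth$hand_position)
  a1 <- parameterize_by_arc(tr1)
  a2 <- parameterize_by_arc(tr2)
  ref <- make_ref(a1$position, a1$sbar)
  expect_equal(euclidean_similarity(a1, ref, 0.1, 0.9),
               euclidean_similarity(a2, ref, 0.1, 0.9), tolerance = 1e-9)
  expect_equal(direction_change_rms(a1, 0.1, 0.9),
               direction_change_rms(a2, 0.1, 0.9), tolerance = 1e-9)
})
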