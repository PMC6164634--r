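# Synthetic task generator: ground-truth-labelled recordings emulating
# reach-grasp-transfer-release-return executions across impairment groups,
# so every pipeline stage is testable without clinical data.

minjerk_sigma <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
minjerk_dsigma <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
# smooth 0 -> 1 -> 0 bump with zero boundary velocity and acceleration
bump_shape <- function(u) ifelse(u <= 0.5, minjerk_sigma(2 * u),
                                 minjerk_sigma(2 * (1 - u)))
bump_dshape <- function(u) ifelse(u <= 0.5, 2 * minjerk_dsigma(2 * u),
                                  -2 * minjerk_dsigma(2 * (1 - u)))

#' Minimum-jerk point-to-point stroke
#'
#' Fifth-order polynomial trajectory with zero boundary velocity and
#' acceleration; the speed profile is the classic bell shape with peak speed
#' `1.875 * ||end - start|| / T` at mid-stroke.
#'
#' @param start,end 3-vectors (m).
#' @param T stroke duration (s).
#' @param rate sampling rate (Hz).
#' @return a [time_trajectory()].
#' @export
minimum_jerk_stroke <- function(start, end, T, rate = 100) {
  stopifnot_contract(T > 0, "duration must be positive")
  t <- seq(0, T, by = 1 / rate)
  tau <- t / T
  pos <- outer(minjerk_sigma(tau), end - start) +
    matrix(start, length(t), 3, byrow = TRUE)
  time_trajectory(t, pos)
}

#' Impairment profile for the synthetic generator
#'
#' Group-dependent movement degradation: duration scaling, corrective
#' submovements superposed on each stroke, band-limited (4-8 Hz) kinetic
#' tremor on the distal joints, sagittal trunk lean during reach, and EMG
#' co-activation / grasp-effort levels. The healthy profile (`H`) is free of
#' submovements, tremor and lean beyond the noise floor; impairment fields
#' increase monotonically from `H` through `AF3` (affected arm, normal
#' execution) to `AF2` (affected arm, moderate execution); `UAF` is the
#' patients' unaffected arm.
#'
#' @param group one of `"H"`, `"UAF"`, `"AF3"`, `"AF2"`.
#' @param ... named overrides of individual fields.
#' @return list of class `impairment_profile`.
#' @export
impairment_profile <- function(group = c("H", "UAF", "AF3", "AF2"), ...) {
  group <- match.arg(group)
  base <- switch(group,
    H   = list(duration_scale = 1.0, n_submovements = 0L,
               submovement_amp = 0,    tremor_amplitude = 0,
               trunk_lean_peak = 0.01, trunk_wobble = 0.002,
               coactivation_level = 0.05, grasp_effort = 0.33),
    UAF = list(duration_scale = 1.1, n_submovements = 0L,
               submovement_amp = 0,    tremor_amplitude = 0.01,
               trunk_lean_peak = 0.02, trunk_wobble = 0.002,
               coactivation_level = 0.10, grasp_effort = 0.40),
    AF3 = list(duration_scale = 1.5, n_submovements = 2L,
               submovement_amp = 0.04, tremor_amplitude = 0.05,
               trunk_lean_peak = 0.05, trunk_wobble = 0.003,
               coactivation_level = 0.30, grasp_effort = 0.55),
    AF2 = list(duration_scale = 3.0, n_submovements = 4L,
               submovement_amp = 0.06, tremor_amplitude = 0.12,
               trunk_lean_peak = 0.15, trunk_wobble = 0.004,
               coactivation_level = 0.60, grasp_effort = 0.95))
  over <- list(...)
  base[names(over)] <- over
  structure(c(list(group = group), base), class = "impairment_profile")
}

# Joint-space posture library (rad) realizing the task waypoints; Cartesian
# waypoints are derived from these by forward kinematics, keeping the
# construction free of inverse kinematics.
task_postures <- function(subtest) {
  # chosen so consecutive strokes meet at distinct corners in hand space
  # (reach forward-down to the table, lift up to the shelf, return), the
  # geometry that makes the stop-and-turn segmentation signature visible
  rest <- c(-0.20, 0.05, 0, 1.35, 0, 0, 0)  # hand in the lap, near the body
  switch(subtest,
    grasp = list(rest, c(-0.55, -0.10, 0, 0.25, 0, 0, 0),
                 c(-1.50, -0.05, 0.1, 0.90, 0, 0, 0), rest),
    grip  = list(rest, c(-0.60, -0.25, 0, 0.30, 0, 0, 0),
                 c(-0.60, 0.20, 0, 0.30, 0, 0, 0), rest),
    pinch = list(rest, c(-0.50, -0.08, 0, 0.20, 0, 0, 0),
                 c(-1.50, -0.03, 0.1, 0.90, 0, 0, 0), rest),
    gross = list(rest, c(-1.10, -0.35, 0.2, 1.90, 0.3, 0, 0), rest))
}

#' Task descriptor for the synthetic generator
#'
#' Grasp, grip and pinch tasks follow the five-phase structure
#' reach-to-grasp / grasp / transfer / release / return (three movement
#' phases); the gross-movement task moves the hand to the head and back
#' (two movement phases). Block side lengths of 25/50/75/100 mm set the
#' grasp-force proxy used by the EMG synthesis.
#'
#' @param subtest `"grasp"`, `"grip"`, `"pinch"` or `"gross"`.
#' @param object_size object (block side) size in meters.
#' @param stroke_durations healthy-profile stroke durations (s); scaled by
#'   the impairment profile.
#' @param dwell_durations manipulation dwell durations (s).
#' @return list of class `task_spec` (Cartesian `waypoints` are filled in by
#'   [generate_task()] from the posture library).
#' @export
task_spec <- function(subtest = c("grasp", "grip", "pinch", "gross"),
                      object_size = 0.05,
                      stroke_durations = NULL, dwell_durations = NULL) {
  subtest <- match.arg(subtest)
  stopifnot_contract(object_size > 0, "object_size must be positive")
  m <- if (subtest == "gross") 2L else 3L
  if (is.null(stroke_durations)) {
    stroke_durations <- if (m == 3) c(1.1, 1.3, 1.2) else c(1.2, 1.2)
  }
  if (is.null(dwell_durations)) {
    dwell_durations <- if (m == 3) c(0.5, 0.5) else 0.3
  }
  stopifnot_contract(length(stroke_durations) == m,
                     "need one duration per movement phase")
  stopifnot_contract(all(dwell_durations >= 0), "dwells must be >= 0")
  structure(list(subtest = subtest, object_size = object_size,
                 expected_movement_phases = m,
                 stroke_durations = stroke_durations,
                 dwell_durations = dwell_durations,
                 postures = task_postures(subtest)),
            class = "task_spec")
}

# body angular rates of an attitude (world-from-body) quaternion series
body_rates_from_quat <- function(quats, dt) {
  n <- nrow(quats)
  w <- matrix(0, n, 3)
  for (k in 2:(n - 1)) {
    dq <- (quats[k + 1, ] - quats[k - 1, ]) / (2 * dt)
    w[k, ] <- 2 * quat_multiply(quat_conj(quats[k, ]), dq)[2:4]
  }
  w[1, ] <- w[2, ]
  w[n, ] <- w[n - 1, ]
  w
}

second_derivative <- function(x, dt) {
  n <- length(x)
  d2 <- numeric(n)
  d2[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d2[1] <- d2[2]
  d2[n] <- d2[n - 1]
  d2
}

#' Generate a ground-truth-labelled synthetic task recording
#'
#' Synthesizes a joint-space trajectory (holds, minimum-jerk strokes and
#' manipulation dwells per the task's phase structure), applies the
#' impairment profile (duration scaling, corrective submovements, 4-8 Hz
#' kinetic tremor windowed to the strokes, sagittal trunk lean ramping
#' during reach), and derives all sensor streams from it: the hand path via
#' forward kinematics, arm gyroscopes via the gyroscope Jacobian plus the
#' trunk rotation coupling, accelerometers as gravity plus linear
#' acceleration in the sensor frame, magnetometers as the rotated reference
#' field, and an 8-channel EMG recording with grasp bursts proportional to
#' the object-size force proxy plus a maximal-effort segment for
#' normalization. Identical inputs and seed give bit-identical recordings.
#'
#' @param task a [task_spec()].
#' @param profile an [impairment_profile()].
#' @param seed integer seed controlling every random element.
#' @param fs IMU sampling rate (Hz).
#' @param emg_fs EMG sampling rate (Hz).
#' @param model an [arm_model()].
#' @param streams `TRUE` (all streams), `FALSE` (ground truth only, much
#'   faster) or `"emg"` (EMG streams only; the hand path and IMU streams are
#'   skipped).
#' @return list of class `synthetic_recording` with elements `truth`
#'   (joint trajectories, hand path, phase boundaries, trunk profile, grasp
#'   force level) and `streams` (`imu` long-format data frame, `emg` data
#'   frame with a `segment` column separating the task from the
#'   maximal-effort segment).
#' @export
generate_task <- function(task, profile = impairment_profile("H"), seed = 1,
                          fs = 100, emg_fs = 200, model = arm_model(),
                          streams = TRUE) {
  stopifnot_contract(inherits(task, "task_spec"), "task must be a task_spec")
  stopifnot_contract(inherits(profile, "impairment_profile"),
                     "profile must be an impairment_profile")
  withr::with_seed(as.integer(seed), {
    dt <- 1 / fs
    m <- task$expected_movement_phases
    reach <- sum(model$segment_lengths)
    # jitter postures (rest posture shared by first and last waypoint)
    post <- task$postures
    for (i in seq_along(post)[-c(1, length(post))]) {
      post[[i]] <- post[[i]] + runif(7, -0.04, 0.04)
    }
    post[[length(post)]] <- post[[1]]
    waypoints <- t(vapply(post, function(q)
      forward_kinematics(model, q)$position, numeric(3)))
    stopifnot_contract(all(row_norms(waypoints) <= reach + 1e-9),
                       "unreachable waypoint for the given segment lengths")
    hold0 <- 1.5
    hold1 <- 1.0
    strokeT <- task$stroke_durations * profile$duration_scale *
      runif(m, 0.9, 1.1)
    dwellT <- task$dwell_durations * runif(length(task$dwell_durations),
                                           0.9, 1.1)
    # segment table: type, duration, from-posture, to-posture
    segs <- list(list(type = "hold", dur = hold0, qa = post[[1]]))
    for (i in seq_len(m)) {
      segs <- c(segs, list(list(type = "stroke", dur = strokeT[i],
                                qa = post[[i]], qb = post[[i + 1]])))
      if (i < m) {
        segs <- c(segs, list(list(type = "dwell", dur = dwellT[i],
                                  qa = post[[i + 1]])))
      }
    }
    segs <- c(segs, list(list(type = "hold", dur = hold1, qa = post[[1]])))
    total <- sum(vapply(segs, `[[`, numeric(1), "dur"))
    t <- seq(0, total, by = dt)
    n <- length(t)
    q <- matrix(0, n, 7)
    qd <- matrix(0, n, 7)
    t0 <- 0
    stroke_bounds <- matrix(NA_real_, m, 2)
    si <- 0
    for (sg in segs) {
      t1 <- t0 + sg$dur
      mask <- t >= t0 - 1e-12 & t <= t1 + 1e-12
      if (sg$type == "stroke") {
        si <- si + 1
        stroke_bounds[si, ] <- c(t0, t1)
        tau <- (t[mask] - t0) / sg$dur
        dqv <- sg$qb - sg$qa
        q[mask, ] <- outer(minjerk_sigma(tau), dqv) +
          matrix(sg$qa, sum(mask), 7, byrow = TRUE)
        qd[mask, ] <- outer(minjerk_dsigma(tau) / sg$dur, dqv)
        # corrective submovements: smooth out-and-back joint-space bumps
        for (k in seq_len(profile$n_submovements)) {
          A <- rnorm(7, 0, profile$submovement_amp)
          dsub <- min(runif(1, 0.5, 0.9), 0.8 * sg$dur)
          tc <- t0 + runif(1, 0.15, 0.85) * sg$dur
          lo <- max(t0, tc - dsub / 2)
          u <- (t - lo) / dsub
          bm <- mask & u >= 0 & u <= 1
          if (any(bm)) {
            q[bm, ] <- q[bm, ] + outer(bump_shape(u[bm]), A)
            qd[bm, ] <- qd[bm, ] + outer(bump_dshape(u[bm]) / dsub, A)
          }
        }
      } else {
        q[mask, ] <- matrix(sg$qa, sum(mask), 7, byrow = TRUE)
      }
      t0 <- t1
    }
    # kinetic tremor on the distal joints, windowed to the strokes
    if (profile$tremor_amplitude > 0) {
      env <- numeric(n)
      denv <- numeric(n)
      for (i in seq_len(m)) {
        mask <- t >= stroke_bounds[i, 1] & t <= stroke_bounds[i, 2]
        tau <- (t[mask] - stroke_bounds[i, 1]) / diff(stroke_bounds[i, ])
        env[mask] <- sin(pi * tau)^2
        denv[mask] <- pi * sin(2 * pi * tau) / diff(stroke_bounds[i, ])
      }
      for (j in 5:7) {
        th_tr <- numeric(n)
        om_tr <- numeric(n)
        for (c3 in 1:3) {
          f <- runif(1, 4, 8)
          ph <- runif(1, 0, 2 * pi)
          vamp <- profile$tremor_amplitude * sqrt(2 / 3)
          a <- vamp / (2 * pi * f)
          th_tr <- th_tr + a * sin(2 * pi * f * t + ph)
          om_tr <- om_tr + vamp * cos(2 * pi * f * t + ph)
        }
        q[, j] <- q[, j] + env * th_tr
        qd[, j] <- qd[, j] + env * om_tr + denv * th_tr
      }
    }
    # trunk profile: sagittal lean rising during the first stroke, held,
    # released during the last stroke; slow wobble on all axes
    lean <- numeric(n)
    r1 <- stroke_bounds[1, ]
    rl <- stroke_bounds[m, ]
    lean[t >= r1[1] & t <= r1[2]] <-
      minjerk_sigma((t[t >= r1[1] & t <= r1[2]] - r1[1]) / diff(r1))
    lean[t > r1[2] & t < rl[1]] <- 1
    lean[t >= rl[1] & t <= rl[2]] <-
      1 - minjerk_sigma((t[t >= rl[1] & t <= rl[2]] - rl[1]) / diff(rl))
    trunk <- matrix(0, n, 3)
    trunk[, 2] <- profile$trunk_lean_peak * lean
    for (ax in 1:3) {
      f <- runif(1, 0.3, 0.8)
      ph <- runif(1, 0, 2 * pi)
      trunk[, ax] <- trunk[, ax] + profile$trunk_wobble *
        sin(2 * pi * f * t + ph)
    }
    trunk_df <- data.frame(t = t, phi = trunk[, 1], theta = trunk[, 2],
                           psi = trunk[, 3])

    # forward pass: hand path (trunk frame) and, if requested, sensor frames
    emg_only <- identical(streams, "emg")
    full_streams <- isTRUE(streams)
    sens_joints <- model$sensor_joints
    hand <- NULL
    if (!emg_only) {
      hand <- matrix(NA_real_, n, 3)
      if (full_streams) {
        Rs <- lapply(1:3, function(i) vector("list", n))
        Ps <- lapply(1:3, function(i) matrix(NA_real_, n, 3))
        omega_rel <- matrix(NA_real_, n, 9)
      }
      for (k in seq_len(n)) {
        chain <- fk_chain(model, q[k, ])
        hand[k, ] <- chain[[7]]$p
        if (full_streams) {
          J <- arm_jacobian(model, q[k, ])
          omega_rel[k, ] <- J %*% qd[k, ]
          for (s in 1:3) {
            Rs[[s]][[k]] <- chain[[sens_joints[[s]]]]$R
            Ps[[s]][k, ] <- chain[[sens_joints[[s]]]]$p
          }
        }
      }
    }
    # ground-truth phase boundaries, also in normalized arc length
    if (!emg_only) {
      spd <- row_norms(apply(hand, 2, num_gradient, t = t))
      s_cum <- c(0, cumsum(diff(t) * (head(spd, -1) + tail(spd, -1)) / 2))
      L <- s_cum[n]
      sbar_at <- function(tt) approx(t, s_cum, xout = tt)$y / L
    } else {
      L <- NA_real_
      sbar_at <- function(tt) rep(NA_real_, length(tt))
    }
    phases <- data.frame(
      index = seq_len(m),
      kind = if (m == 3) c("reach_to_grasp", "transfer", "return")
             else c("reach_to_grasp", "return"),
      t_onset = stroke_bounds[, 1], t_term = stroke_bounds[, 2],
      sbar_onset = sbar_at(stroke_bounds[, 1]),
      sbar_term = sbar_at(stroke_bounds[, 2])
    )
    grasp_force <- profile$grasp_effort * task$object_size / 0.1

    truth <- list(t = t, angles = q, speeds = qd, hand_position = hand,
                  trunk = trunk_df, phases = phases, L = L,
                  grasp_force = grasp_force, waypoints = waypoints,
                  initial_angles = post[[1]],
                  stroke_durations = strokeT, dwell_durations = dwellT)

    streams_out <- NULL
    if (full_streams || emg_only) {
      imu <- NULL
    }
    if (full_streams) {
      g_up <- c(0, 0, 9.81)
      m_ref <- c(0.5, 0, -sqrt(3) / 2)
      # trunk attitude (world-from-body) and body rates
      quats <- matrix(NA_real_, n, 4)
      for (k in seq_len(n)) {
        quats[k, ] <- quat_from_matrix(
          euler_zyx_to_matrix(trunk[k, 1], trunk[k, 2], trunk[k, 3]))
        if (k > 1 && sum(quats[k, ] * quats[k - 1, ]) < 0) {
          quats[k, ] <- -quats[k, ]
        }
      }
      w_trunk <- body_rates_from_quat(quats, dt)
      WT <- lapply(seq_len(n), function(k) quat_to_matrix(quats[k, ]))
      sensor_ids <- c("R_upper", "R_wrist", "R_hand")
      imu_list <- vector("list", 4)
      for (s in 1:3) {
        # world positions and linear acceleration of the sensor
        pw <- t(vapply(seq_len(n), function(k)
          as.numeric(WT[[k]] %*% Ps[[s]][k, ]), numeric(3)))
        acc_w <- apply(pw, 2, second_derivative, dt = dt)
        gyro <- matrix(NA_real_, n, 3)
        accel <- matrix(NA_real_, n, 3)
        magn <- matrix(NA_real_, n, 3)
        for (k in seq_len(n)) {
          Rws <- WT[[k]] %*% Rs[[s]][[k]]
          gyro[k, ] <- crossprod(Rs[[s]][[k]], w_trunk[k, ]) +
            omega_rel[k, (3 * s - 2):(3 * s)]
          accel[k, ] <- crossprod(Rws, acc_w[k, ] + g_up)
          magn[k, ] <- crossprod(Rws, m_ref)
        }
        imu_list[[s]] <- data.frame(t = t, sensor_id = sensor_ids[s],
                                    gx = gyro[, 1], gy = gyro[, 2],
                                    gz = gyro[, 3], ax = accel[, 1],
                                    ay = accel[, 2], az = accel[, 3],
                                    mx = magn[, 1], my = magn[, 2],
                                    mz = magn[, 3])
      }
      # trunk sensor
      gyro <- w_trunk
      accel <- magn <- matrix(NA_real_, n, 3)
      for (k in seq_len(n)) {
        W <- quat_to_matrix(quats[k, ])
        accel[k, ] <- crossprod(W, g_up)
        magn[k, ] <- crossprod(W, m_ref)
      }
      imu_list[[4]] <- data.frame(t = t, sensor_id = "trunk",
                                  gx = gyro[, 1], gy = gyro[, 2],
                                  gz = gyro[, 3], ax = accel[, 1],
                                  ay = accel[, 2], az = accel[, 3],
                                  mx = magn[, 1], my = magn[, 2],
                                  mz = magn[, 3])
      imu <- do.call(rbind, imu_list)
    }
    if (full_streams || emg_only) {
      # EMG: amplitude-modulated Gaussian noise, grasp burst spanning the
      # grasp-to-release interval, plus a maximal-effort segment
      te <- seq(0, total, by = 1 / emg_fs)
      floor_lvl <- 0.03 + 0.15 * profile$coactivation_level
      env <- rep(floor_lvl, length(te))
      if (m == 3) {
        t_g0 <- stroke_bounds[1, 2]
        t_g1 <- stroke_bounds[3, 1]
        ramp <- 0.2
        s3 <- function(u) {
          u <- pmin(pmax(u, 0), 1)
          u^2 * (3 - 2 * u)
        }
        burst <- grasp_force *
          s3((te - (t_g0 - ramp)) / ramp) * s3(((t_g1 + ramp) - te) / ramp)
        env <- pmax(env, burst)
      }
      gains <- runif(8, 0.7, 1.3)
      emg_task <- sapply(1:8, function(nch)
        gains[nch] * env * rnorm(length(te)))
      te_max <- seq(0, 2, by = 1 / emg_fs)
      emg_max <- sapply(1:8, function(nch)
        gains[nch] * 1.0 * rnorm(length(te_max)))
      emg <- rbind(
        data.frame(t = te, segment = "task", emg_task),
        data.frame(t = te_max + total + 1, segment = "max_effort", emg_max))
      names(emg) <- c("t", "segment", paste0("e", 1:8))
      streams_out <- list(imu = imu, emg = emg)
    }

    structure(list(task = task, profile = profile, seed = as.integer(seed),
                   fs = fs, emg_fs = emg_fs, model = model,
                   truth = truth, streams = streams_out),
              class = "synthetic_recording")
  })
}

#' Corrupt the IMU streams of a synthetic recording
#'
#' Adds seeded white noise and constant per-channel bias to the gyroscope
#' and accelerometer channels. The ground truth is untouched.
#'
#' @param rec a `synthetic_recording` with streams.
#' @param gyro_noise_sd,accel_noise_sd white-noise standard deviations
#'   (rad/s, m/s^2).
#' @param gyro_bias constant additive gyro bias (rad/s), applied to every
#'   gyro channel.
#' @param seed noise seed.
#' @return the recording with corrupted IMU streams.
#' @export
corrupt_sensors <- function(rec, gyro_noise_sd = 0.005, gyro_bias = 0,
                            accel_noise_sd = 0.05, seed = 1) {
  stopifnot_contract(inherits(rec, "synthetic_recording"),
                     "rec must be a synthetic_recording")
  stopifnot_contract(!is.null(rec$streams), "recording has no streams")
  stopifnot_contract(gyro_noise_sd >= 0 && accel_noise_sd >= 0,
                     "noise parameters must be >= 0")
  withr::with_seed(as.integer(seed), {
    imu <- rec$streams$imu
    ng <- nrow(imu)
    for (col in c("gx", "gy", "gz")) {
      imu[[col]] <- imu[[col]] + gyro_bias +
        if (gyro_noise_sd > 0) rnorm(ng, 0, gyro_noise_sd) else 0
    }
    for (col in c("ax", "ay", "az")) {
      imu[[col]] <- imu[[col]] +
        if (accel_noise_sd > 0) rnorm(ng, 0, accel_noise_sd) else 0
    }
    rec$streams$imu <- imu
    rec
  })
}
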