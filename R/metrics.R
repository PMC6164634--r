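#' Movement time per phase and for the whole task
#'
#' Phase movement time is the difference between the refined termination and
#' onset times; task movement time spans from the first movement-phase onset
#' to the last movement-phase termination, dwells included.
#'
#' @param seg a `segmentation` from [segment_phases()].
#' @return data frame `phase, kind, T_m` with one row per movement phase and
#'   a final `task` row.
#' @export
movement_time <- function(seg) {
  mov <- seg$phases[seg$movement_phase_indices, , drop = FALSE]
  out <- data.frame(
    phase = as.character(mov$index),
    kind = mov$kind,
    T_m = mov$t_term - mov$t_onset,
    stringsAsFactors = FALSE
  )
  rbind(out, data.frame(phase = "task", kind = "task",
                        T_m = max(mov$t_term) - min(mov$t_onset)))
}

#' Rotational jerk index of the hand
#'
#' Log dimensionless jerk computed from the hand gyroscope: the angular
#' velocity is zero-phase low-pass filtered, its second time derivative is
#' estimated with fourth-order central differences, and
#' \deqn{\eta_{rot} = \log\left(\frac{T^5}{\theta_p^2}
#'   \int_{T_o}^{T_t} \Vert\ddot\omega(t)\Vert^2\, dt\right),}
#' a dimensionless quantity; lower values indicate smoother movement.
#' The amplitude normalization \eqn{\theta_p} defaults to 1, appropriate for
#' tasks in which hand orientation is held (a configuration hook is exposed
#' for tasks with substantial angular displacement).
#'
#' @param omega n x 3 matrix of hand angular velocity (rad/s).
#' @param t timestamps (s), uniform.
#' @param t_onset,t_term phase onset and termination times (s).
#' @param theta_p angular-displacement normalization (default 1).
#' @param cutoff_hz low-pass cutoff before differentiation (Hz).
#' @return scalar; `-Inf` with attribute `undefined_smoothness = TRUE` when
#'   the angular velocity is constant over the phase.
#' @export
rotational_jerk_index <- function(omega, t, t_onset, t_term, theta_p = 1,
                                  cutoff_hz = 10) {
  omega <- as.matrix(omega)
  stopifnot_contract(ncol(omega) == 3, "omega must be n x 3")
  dt <- check_uniform_dt(t)
  fs <- 1 / dt
  idx <- which(t >= t_onset & t <= t_term)
  if (length(idx) < 10) {
    abort_aq("araquant_error_contract",
             "phase too short for jerk estimation (need >= 10 samples)")
  }
  w <- omega[idx, , drop = FALSE]
  # constant angular velocity: zero rotational jerk, smoothness undefined
  if (max(abs(sweep(w, 2, w[1, ]))) < 1e-12) {
    return(structure(-Inf, undefined_smoothness = TRUE))
  }
  if (cutoff_hz > 0 && cutoff_hz < fs / 2 && nrow(w) > 12) {
    bf <- signal::butter(2, cutoff_hz / (fs / 2))
    w <- apply(w, 2, function(col) signal::filtfilt(bf, col))
  }
  # fourth-order central second derivative; two samples lost at each end
  n <- nrow(w)
  if (n < 10) abort_aq("araquant_error_contract", "phase too short")
  d2 <- (-w[1:(n - 4), ] + 16 * w[2:(n - 3), ] - 30 * w[3:(n - 2), ] +
           16 * w[4:(n - 1), ] - w[5:n, ]) / (12 * dt^2)
  jerk2 <- rowSums(d2^2)
  tt <- t[idx][3:(n - 2)]
  integral <- trapz_(tt, jerk2)
  Tm <- t_term - t_onset
  if (integral <= 0) {
    return(structure(-Inf, undefined_smoothness = TRUE))
  }
  log(Tm^5 / theta_p^2 * integral)
}

#' Build the healthy-group reference trajectory for a task
#'
#' Coordinate-wise median across arc-parameterized trajectories on a common
#' normalized-arc-length grid (lower-median convention for even counts, so
#' the reference is always an observed value), with per-point interquartile
#' ranges as dispersion.
#'
#' @param arcs list of `arc_trajectory` objects (>= 3) on identical grids.
#' @return object of class `reference_trajectory` with `sbar`, `position`
#'   (median path), `iqr` (per-point, per-coordinate IQR).
#' @export
build_reference <- function(arcs) {
  stopifnot_contract(length(arcs) >= 3, "need at least 3 trajectories")
  grids <- lapply(arcs, `[[`, "sbar")
  same <- all(vapply(grids[-1], function(g)
    length(g) == length(grids[[1]]) && max(abs(g - grids[[1]])) < 1e-12,
    logical(1)))
  stopifnot_contract(same, "trajectories must share the arc-length grid")
  n <- length(grids[[1]])
  med <- matrix(NA_real_, n, 3)
  iqr <- matrix(NA_real_, n, 3)
  for (c3 in 1:3) {
    vals <- vapply(arcs, function(a) a$position[, c3], numeric(n))
    med[, c3] <- apply(vals, 1, lower_median)
    iqr[, c3] <- apply(vals, 1, function(v)
      diff(quantile(v, c(0.25, 0.75), names = FALSE)))
  }
  structure(list(sbar = grids[[1]], position = med, iqr = iqr),
            class = "reference_trajectory")
}

phase_grid_idx <- function(sbar, sbar_onset, sbar_term) {
  stopifnot_contract(sbar_onset >= 0 && sbar_term <= 1 &&
                       sbar_onset < sbar_term,
                     "phase bounds must satisfy 0 <= onset < term <= 1")
  idx <- which(sbar >= sbar_onset & sbar <= sbar_term)
  stopifnot_contract(length(idx) >= 2, "empty phase interval on the grid")
  idx
}

#' RMS Euclidean distance from the reference trajectory
#'
#' \deqn{D_i = \sqrt{\frac{1}{\bar s_{t} - \bar s_{o}}
#'   \int_{\bar s_o}^{\bar s_t} \Vert p(\bar s) - p_r(\bar s)\Vert^2
#'   d\bar s}}
#' evaluated by trapezoidal quadrature on the common grid. Being a pure
#' function of the path, it is invariant to the time course of the movement.
#'
#' @param arc an `arc_trajectory`.
#' @param ref a `reference_trajectory` on the same grid.
#' @param sbar_onset,sbar_term phase bounds in normalized arc length.
#' @return scalar (meters).
#' @export
euclidean_similarity <- function(arc, ref, sbar_onset = 0, sbar_term = 1) {
  stopifnot_contract(length(arc$sbar) == length(ref$sbar) &&
                       max(abs(arc$sbar - ref$sbar)) < 1e-12,
                     "arc and reference must share the grid")
  idx <- phase_grid_idx(arc$sbar, sbar_onset, sbar_term)
  d2 <- rowSums((arc$position[idx, , drop = FALSE] -
                   ref$position[idx, , drop = FALSE])^2)
  s <- arc$sbar[idx]
  sqrt(trapz_(s, d2) / (s[length(s)] - s[1]))
}

#' Normalized RMS direction change over a phase
#'
#' RMS of the direction-change profile \eqn{\nu(\bar s)} over the phase,
#' divided by \eqn{\pi} (the largest possible change of direction), so the
#' result lies in `[0, 1]`.
#'
#' @inheritParams euclidean_similarity
#' @return dimensionless scalar in `[0, 1]`.
#' @export
direction_change_rms <- function(arc, sbar_onset = 0, sbar_term = 1) {
  idx <- phase_grid_idx(arc$sbar, sbar_onset, sbar_term)
  s <- arc$sbar[idx]
  sqrt(trapz_(s, arc$nu[idx]^2) / (s[length(s)] - s[1])) / pi
}

#' Similarity weights
#'
#' Equal weights `alpha = 0.5` per meter and `beta = 0.5` (dimensionless)
#' are the defaults: the two components have similar magnitudes in
#' measurements.
#'
#' @param alpha weight of the RMS Euclidean distance (1/m).
#' @param beta weight of the normalized direction change.
#' @export
similarity_weights <- function(alpha = 0.5, beta = 0.5) {
  stopifnot_contract(alpha >= 0 && beta >= 0, "weights must be >= 0")
  list(alpha = alpha, beta = beta)
}

#' Combined trajectory-similarity parameter
#'
#' \eqn{\chi_i = \alpha D_i + \beta \hat\nu_i}.
#'
#' @param D RMS Euclidean distance (m), see [euclidean_similarity()].
#' @param nu_hat normalized RMS direction change, see
#'   [direction_change_rms()].
#' @param weights a [similarity_weights()] list.
#' @return dimensionless scalar.
#' @export
trajectory_similarity <- function(D, nu_hat, weights = similarity_weights()) {
  stopifnot_contract(D >= 0 && nu_hat >= 0, "inputs must be >= 0")
  weights$alpha * D + weights$beta * nu_hat
}

#' Trunk stability index
#'
#' Maximum over the phase of the root-sum-of-squares deviation of the three
#' trunk rotation angles from their values at phase start:
#' \deqn{\rho_i = \max_t \sqrt{(\varphi-\varphi_0)^2 + (\vartheta-\vartheta_0)^2
#'   + (\psi-\psi_0)^2}.}
#'
#' @param trunk data frame `t, phi, theta, psi` (rad), see
#'   [estimate_trunk_angles()].
#' @param t_onset,t_term phase bounds (s).
#' @return scalar (rad).
#' @export
trunk_stability_index <- function(trunk, t_onset, t_term) {
  idx <- which(trunk$t >= t_onset & trunk$t <= t_term)
  stopifnot_contract(length(idx) >= 1, "phase outside trunk angle support")
  a0 <- c(trunk$phi[idx[1]], trunk$theta[idx[1]], trunk$psi[idx[1]])
  dev <- cbind(trunk$phi[idx] - a0[1], trunk$theta[idx] - a0[2],
               trunk$psi[idx] - a0[3])
  max(sqrt(rowSums(wrap_angle(dev)^2)))
}

#' Phase EMG intensity across all eight electrodes
#'
#' \deqn{\hat w_i = \sqrt{\frac{1}{T_{mi}} \int_{T_o}^{T_t}
#'   \sum_{n=1}^{8} w_n^2(t)\, dt}}
#' by trapezoidal quadrature; combining all electrodes makes the value
#' insensitive to armband orientation.
#'
#' @param emg data frame with column `t` (s) and exactly eight channel
#'   columns `e1..e8`.
#' @param t_onset,t_term phase bounds (s).
#' @return scalar (amplifier units).
#' @export
emg_rms <- function(emg, t_onset, t_term) {
  ch <- grep("^e[0-9]+$", names(emg), value = TRUE)
  stopifnot_contract(length(ch) == 8, "EMG recording must have 8 channels")
  idx <- which(emg$t >= t_onset & emg$t <= t_term)
  stopifnot_contract(length(idx) >= 2, "phase outside EMG support")
  ssq <- rowSums(as.matrix(emg[idx, ch])^2)
  tt <- emg$t[idx]
  unname(sqrt(trapz_(tt, ssq) / (tt[length(tt)] - tt[1])))
}

#' Normalize phase EMG by the maximal-effort value
#'
#' Ratio of the phase EMG intensity to \eqn{\hat w_{MAX}}, the value of
#' [emg_rms()] over a designated maximal-effort (dynamometry) recording.
#' Values above 1 are permitted but flagged: they indicate a submaximal
#' reference.
#'
#' @param w_hat phase EMG intensity.
#' @param w_max maximal-effort EMG intensity, > 0.
#' @return scalar with attribute `submaximal_reference` when the ratio
#'   exceeds 1.
#' @export
emg_normalize <- function(w_hat, w_max) {
  stopifnot_contract(w_max > 0, "w_max must be > 0")
  r <- w_hat / w_max
  if (r > 1) {
    warning("normalized EMG exceeds 1: maximal-effort reference is submaximal")
    attr(r, "submaximal_reference") <- TRUE
  }
  r
}
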