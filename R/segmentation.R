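#' Time-domain hand trajectory container
#'
#' @param t numeric n-vector of uniformly spaced timestamps (s).
#' @param position n x 3 matrix of hand positions (m, trunk frame).
#' @return object of class `time_trajectory` with derived `speed`
#'   (\eqn{\|\dot p(t)\|}, central differences).
#' @export
time_trajectory <- function(t, position) {
  position <- as.matrix(position)
  stopifnot_contract(ncol(position) == 3, "position must be n x 3")
  stopifnot_contract(nrow(position) >= 10, "need at least 10 samples")
  stopifnot_contract(all(is.finite(position)) && all(is.finite(t)),
                     "trajectory must be finite")
  check_uniform_dt(t)
  vel <- apply(position, 2, num_gradient, t = t)
  structure(list(t = t, position = position, velocity = vel,
                 speed = row_norms(vel)),
            class = "time_trajectory")
}

#' Arc length profile of a trajectory
#'
#' Cumulative arc length \eqn{s(t) = \int_0^t \|\dot p\| dt} by trapezoidal
#' quadrature of the speed profile, and the total path length `L = s(T)`.
#'
#' @param traj a [time_trajectory()].
#' @return list with `t`, `s` (monotone non-decreasing, `s[1] = 0`), `L`.
#' @export
arc_length_profile <- function(traj) {
  stopifnot_contract(inherits(traj, "time_trajectory"),
                     "traj must be a time_trajectory")
  dt <- diff(traj$t)
  incr <- dt * (head(traj$speed, -1) + tail(traj$speed, -1)) / 2
  s <- c(0, cumsum(incr))
  list(t = traj$t, s = s, L = s[length(s)])
}

#' Re-parameterize a trajectory by normalized arc length
#'
#' Resamples the hand path on a uniform grid of the normalized arc length
#' \eqn{\bar s = s(t)/L \in [0, 1]}. Consecutive time samples where the
#' movement speed is (near) zero advance the arc length by nothing and
#' therefore collapse to a single arc-domain point, which makes the
#' representation independent of dwell durations. The initial position is
#' subtracted so the path starts at the origin.
#'
#' @param traj a [time_trajectory()].
#' @param dsbar grid step of the normalized arc length (default 1/500).
#' @param zero_speed_frac speeds below this fraction of the peak speed are
#'   treated as zero for the collapse rule.
#' @return object of class `arc_trajectory` with fields `sbar`, `position`
#'   (origin-shifted), `distance` \eqn{d(\bar s)}, `speed`, `nu` (direction
#'   change, see [direction_change()]), `L`, `time_map` (matched times, see
#'   [arc_to_time()]) and `source` (the input trajectory).
#' @export
parameterize_by_arc <- function(traj, dsbar = 1 / 500,
                                zero_speed_frac = 0.02) {
  prof <- arc_length_profile(traj)
  if (prof$L <= 0 || max(traj$speed) <= 0) {
    abort_aq("araquant_error_degenerate",
             "degenerate trajectory: total path length is zero")
  }
  sbar_t <- prof$s / prof$L
  # collapse zero-velocity runs: keep the first sample of each run so the
  # s grid used for interpolation is strictly increasing
  thr <- zero_speed_frac * max(traj$speed)
  moving <- traj$speed > thr
  keep <- c(TRUE, diff(sbar_t) > .Machine$double.eps * 10 & moving[-1])
  keep[length(keep)] <- TRUE
  st <- sbar_t[keep]
  # enforce strict monotonicity for interpolation
  ord <- !duplicated(st)
  st <- st[ord]
  pos_kept <- traj$position[keep, , drop = FALSE][ord, , drop = FALSE]
  spd_kept <- traj$speed[keep][ord]
  t_kept <- traj$t[keep][ord]
  grid <- seq(0, 1, by = dsbar)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  interp <- function(y) approx(st, y, xout = grid, rule = 2)$y
  pos <- cbind(interp(pos_kept[, 1]), interp(pos_kept[, 2]),
               interp(pos_kept[, 3]))
  speed <- interp(spd_kept)
  p0 <- pos[1, ]
  pos <- sweep(pos, 2, p0)
  arc <- structure(list(
    sbar = grid,
    position = pos,
    distance = row_norms(pos),
    speed = speed,
    L = prof$L,
    nu = NULL,
    time_map = NULL,
    zero_speed_thr = thr,
    source = traj
  ), class = "arc_trajectory")
  arc$nu <- direction_change(arc)
  arc$time_map <- arc_to_time(arc, traj, grid)
  arc
}

#' Direction-change profile along an arc-parameterized path
#'
#' Angle between unit tangent vectors at successive grid points,
#' \eqn{\nu(\bar s) = \mathrm{atan2}(\|r \times r'\|, r \cdot r')}, which is
#' confined to \eqn{[0, \pi]}. Zero-length tangents (duplicate points) are
#' skipped and filled by linear interpolation.
#'
#' @param arc an `arc_trajectory` (only `position` is used).
#' @return numeric vector of the same length as the grid; the two endpoint
#'   values are zero by convention.
#' @export
direction_change <- function(arc) {
  pos <- arc$position
  n <- nrow(pos)
  stopifnot_contract(n >= 3, "need at least 3 arc samples")
  seg <- diff(pos)
  len <- row_norms(seg)
  nu <- rep(NA_real_, n)
  nu[1] <- 0
  nu[n] <- 0
  for (k in 2:(n - 1)) {
    if (len[k - 1] > 0 && len[k] > 0) {
      r1 <- seg[k - 1, ] / len[k - 1]
      r2 <- seg[k, ] / len[k]
      nu[k] <- atan2(sqrt(sum(pracma::cross(r1, r2)^2)), sum(r1 * r2))
    }
  }
  bad <- is.na(nu)
  if (any(bad)) {
    nu[bad] <- approx(which(!bad), nu[!bad], xout = which(bad), rule = 2)$y
  }
  nu
}

# Prominence of local maxima: for each interior peak, walk outward to the
# nearest higher point on each side and take the minimum in between; the
# prominence is peak height minus the larger of the two bracketing minima.
peak_prominence <- function(x) {
  n <- length(x)
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(idx) == 0) return(data.frame(index = integer(), prom = numeric()))
  prom <- vapply(idx, function(i) {
    lo_l <- min(x[1:i])
    j <- which(x[1:i] > x[i])
    if (length(j)) lo_l <- min(x[max(j):i])
    lo_r <- min(x[i:n])
    j <- which(x[i:n] > x[i])
    if (length(j)) lo_r <- min(x[i:(i + min(j) - 1)])
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
  data.frame(index = idx, prom = prom)
}

# interior local minima, tolerating plateaus: within each maximal run of
# equal-or-descending-then-ascending values the run midpoint is reported
local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  d <- diff(x)
  # sign of the last nonzero difference before/after each interior point
  carry <- function(s) {
    for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
    s
  }
  s_before <- carry(sign(d))
  s_after <- rev(carry(rev(sign(d))))
  idx <- which(s_before[-length(s_before)] < 0 & s_after[-1] > 0) + 1L
  if (length(idx) == 0) return(integer())
  # collapse adjacent indices from the same plateau to the midpoint
  grp <- cumsum(c(1L, diff(idx) > 1L))
  vapply(split(idx, grp), function(g) g[ceiling(length(g) / 2)], integer(1),
         USE.NAMES = FALSE)
}

#' Segment an arc-parameterized trajectory into movement phases
#'
#' Candidate phase boundaries are the normalized-arc-length positions where
#' a local maximum of the direction-change profile coincides (within
#' `window` of \eqn{\bar s}) with a local minimum of the speed profile —
#' the signature of a stop-and-turn between movement phases. Candidates
#' closer than `min_sep` are merged (higher prominence wins), then the
#' `expected_movement_phases - 1` most prominent boundaries are retained
#' (ties broken toward earlier \eqn{\bar s}) and phases are laid out between
#' them. Boundaries are mapped back to time ([arc_to_time()]) and refined
#' with the cubic minimum-acceleration onset model ([refine_onset()]);
#' manipulation (grasp/release) phases are the dwell intervals between a
#' refined termination and the following refined onset.
#'
#' @param arc an `arc_trajectory` from [parameterize_by_arc()].
#' @param expected_movement_phases 3 for grasp/grip/pinch tasks, 2 for gross
#'   movement tasks, 1 for a single stroke.
#' @param nu_prominence minimum prominence (rad) of a direction-change peak.
#' @param window coincidence window between speed minimum and direction
#'   change maximum, in units of \eqn{\bar s}.
#' @param min_sep minimum boundary separation in \eqn{\bar s}.
#' @param min_phase_frac minimum fraction of the path a movement phase must
#'   cover; boundaries closer than this to the path ends or to each other
#'   are rejected.
#' @param speed_frac candidate speed minima must lie below this fraction of
#'   the peak speed.
#' @param refine logical: refine onset/termination times with
#'   [refine_onset()].
#' @param onset_window,onset_delta_T parameters passed to [refine_onset()].
#' @return object of class `segmentation`: data frame `phases` with columns
#'   `index, kind, sbar_onset, sbar_term, t_onset, t_term, auto`, plus
#'   `movement_phase_indices` and the candidate diagnostics.
#' @export
segment_phases <- function(arc, expected_movement_phases,
                           nu_prominence = pi / 6, window = 0.02,
                           min_sep = 0.02, min_phase_frac = 0.05,
                           speed_frac = 0.2,
                           refine = TRUE, onset_window = 0.5,
                           onset_delta_T = 0.2) {
  stopifnot_contract(inherits(arc, "arc_trajectory"),
                     "arc must be an arc_trajectory")
  m <- as.integer(expected_movement_phases)
  stopifnot_contract(m >= 1, "expected_movement_phases must be >= 1")
  sbar <- arc$sbar
  # direction-change peaks are detected on the raw profile (smoothing can
  # push a genuine but smeared corner below the prominence threshold); the
  # speed profile is lightly smoothed for minima detection
  smooth3 <- function(x) {
    v <- stats::filter(x, rep(1 / 3, 3), sides = 2)
    v[is.na(v)] <- x[is.na(v)]
    as.numeric(v)
  }
  spd_s <- smooth3(arc$speed)
  peaks <- peak_prominence(arc$nu)
  peaks <- peaks[peaks$prom >= nu_prominence, , drop = FALSE]
  vmin <- local_minima(spd_s)
  win_pts <- max(1L, ceiling(window / (sbar[2] - sbar[1])))
  vthr <- speed_frac * max(spd_s)
  cand <- data.frame(index = integer(), sbar = numeric(), prom = numeric())
  if (nrow(peaks) > 0 && length(vmin) > 0) {
    for (i in seq_len(nrow(peaks))) {
      d <- abs(vmin - peaks$index[i])
      j <- which.min(d)
      if (d[j] <= win_pts && spd_s[vmin[j]] <= vthr) {
        cand <- rbind(cand, data.frame(index = peaks$index[i],
                                       sbar = sbar[peaks$index[i]],
                                       prom = peaks$prom[i]))
      }
    }
  }
  # merge candidates closer than min_sep, keeping the more prominent one
  if (nrow(cand) > 1) {
    cand <- cand[order(cand$sbar), , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (i in 2:nrow(cand)) {
      prev <- max(which(keep[1:(i - 1)]))
      if (cand$sbar[i] - cand$sbar[prev] < min_sep) {
        if (cand$prom[i] > cand$prom[prev]) keep[prev] <- FALSE
        else keep[i] <- FALSE
      }
    }
    cand <- cand[keep, , drop = FALSE]
  }
  # greedy selection by prominence (ties to earlier sbar): every movement
  # phase must cover at least `min_phase_frac` of the path, which rejects
  # spurious high-curvature candidates from low-speed noise meanders right
  # at a stroke onset
  ord <- cand[order(-cand$prom, cand$sbar), , drop = FALSE]
  accepted <- numeric(0)
  for (i in seq_len(nrow(ord))) {
    if (length(accepted) >= m - 1) break
    s_c <- ord$sbar[i]
    if (min(abs(c(0, 1, accepted) - s_c)) >= min_phase_frac) {
      accepted <- c(accepted, s_c)
    }
  }
  if (length(accepted) < m - 1) {
    abort_aq("araquant_error_segmentation",
             sprintf("found %d admissible boundaries, need %d",
                     length(accepted), m - 1),
             data = list(candidates = cand))
  }
  bounds <- sort(accepted)
  lo <- c(0, bounds)
  hi <- c(bounds, 1)
  kinds <- if (m == 3) c("reach_to_grasp", "transfer", "return")
           else if (m == 2) c("reach_to_grasp", "return")
           else rep("transfer", m)
  ds <- sbar[2] - sbar[1]
  traj <- arc$source
  t0 <- traj$t[1]
  t_end <- traj$t[length(traj$t)]
  radius <- 3 * arc$L * ds
  pos <- traj$position
  n_t <- nrow(pos)
  # dwell arrival/departure around a matched boundary time: walk while the
  # hand stays within `radius` of the matched position (robust to sensor
  # noise, which keeps dwell samples jittering but spatially put)
  dwell_walk <- function(t_at, dir) {
    k0 <- which.min(abs(traj$t - t_at))
    k <- k0
    while (k + dir >= 1 && k + dir <= n_t &&
             sqrt(sum((pos[k + dir, ] - pos[k0, ])^2)) < radius) {
      k <- k + dir
    }
    traj$t[k]
  }
  # map all boundaries back to time in one causally ordered pass, then
  # anchor each boundary at its dwell: arrival (termination side) and
  # departure (onset side)
  bt <- arc_to_time(arc, traj, c(0, bounds, 1))
  arr <- c(traj$t[1], vapply(bt[-1], dwell_walk, numeric(1), dir = -1L))
  dep <- vapply(bt[-length(bt)], dwell_walk, numeric(1), dir = 1L)
  onset_t <- dep
  term_t <- arr[-1]
  if (refine) {
    # distance from the true rest position of each dwell (the hand position
    # midway through the dwell), the signal whose departure from / arrival
    # at zero the cubic model fits
    dwell_mid_pos <- function(t_a, t_b) {
      k <- which.min(abs(traj$t - (t_a + t_b) / 2))
      traj$position[k, ]
    }
    for (i in seq_len(m)) {
      p_rest <- dwell_mid_pos(arr[i], dep[i])
      x <- row_norms(sweep(traj$position, 2, p_rest))
      # onset: fit from the arrival at this dwell onward, so the static
      # level is not contaminated by the preceding stroke
      onset_t[i] <- tryCatch({
        keep <- traj$t >= arr[i]
        refine_onset(x[keep], traj$t[keep], dep[i],
                     window = onset_window, delta_T = onset_delta_T,
                     direction = "onset")$t_o
      }, araquant_error_no_onset = function(e) dep[i])
      # termination: fit up to the departure from the next dwell, so the
      # static level is not contaminated by the following stroke
      depart_next <- if (i < m) dep[i + 1] else t_end
      p_rest_next <- dwell_mid_pos(arr[i + 1], depart_next)
      xn <- row_norms(sweep(traj$position, 2, p_rest_next))
      term_t[i] <- tryCatch({
        keep <- traj$t <= depart_next
        refine_onset(xn[keep], traj$t[keep], arr[i + 1],
                     window = onset_window, delta_T = onset_delta_T,
                     direction = "termination")$t_o
      }, araquant_error_no_onset = function(e) arr[i + 1])
    }
  }
  # enforce ordering after refinement
  for (i in seq_len(m)) {
    if (i > 1 && onset_t[i] < term_t[i - 1]) onset_t[i] <- term_t[i - 1]
    if (term_t[i] <= onset_t[i]) term_t[i] <- onset_t[i] +
        (traj$t[2] - traj$t[1])
  }
  phases <- data.frame(
    index = seq_len(m), kind = kinds,
    sbar_onset = lo, sbar_term = hi,
    t_onset = onset_t, t_term = term_t,
    auto = TRUE, stringsAsFactors = FALSE
  )
  # manipulation phases: the dwell intervals between movement phases
  manip <- NULL
  if (m >= 2) {
    mk <- if (m == 3) c("grasp", "release") else rep("hold", m - 1)
    manip <- data.frame(
      index = NA_integer_, kind = mk[seq_len(m - 1)],
      sbar_onset = bounds, sbar_term = bounds,
      t_onset = term_t[-m], t_term = onset_t[-1],
      auto = TRUE, stringsAsFactors = FALSE
    )
  }
  holds <- data.frame(
    index = NA_integer_, kind = c("hold", "hold"),
    sbar_onset = c(0, 1), sbar_term = c(0, 1),
    t_onset = c(t0, term_t[m]), t_term = c(onset_t[1], t_end),
    auto = TRUE, stringsAsFactors = FALSE
  )
  all_ph <- rbind(holds[1, ], do.call(rbind, lapply(seq_len(m), function(i) {
    r <- phases[i, ]
    if (i < m && !is.null(manip)) rbind(r, manip[i, ]) else r
  })), holds[2, ])
  rownames(all_ph) <- NULL
  structure(list(
    phases = all_ph,
    movement_phase_indices = which(!is.na(all_ph$index)),
    candidates = cand
  ), class = "segmentation")
}

#' Map normalized-arc-length points back to time
#'
#' Minimum-distance matching: for each requested arc point the time-domain
#' sample minimizing the Euclidean position distance is located. The search
#' is kept causally consistent by restricting it to samples forward of the
#' previously matched time whose cumulative normalized path length lies in
#' close proximity of the queried arc point, so a path revisiting the same
#' position later is matched to the correct visit. Returned times are
#' strictly increasing.
#'
#' @param arc an `arc_trajectory`.
#' @param traj the source [time_trajectory()].
#' @param points numeric vector of query points in `[0, 1]`.
#' @param proximity half-width of the admissible band of normalized path
#'   length around each query (widened automatically if no sample falls in
#'   it).
#' @return numeric vector of matched times.
#' @export
arc_to_time <- function(arc, traj, points, proximity = 0.01) {
  stopifnot_contract(all(points >= 0 & points <= 1),
                     "points must lie in [0, 1]")
  n <- nrow(traj$position)
  prof <- arc_length_profile(traj)
  snorm <- prof$s / prof$L
  prev <- 0L
  out <- numeric(length(points))
  for (q in seq_along(points)) {
    cand <- integer(0)
    width <- proximity
    while (length(cand) == 0 && width <= 1) {
      cand <- which(abs(snorm - points[q]) <= width)
      cand <- cand[cand > prev]
      width <- width * 5
    }
    if (length(cand) == 0) cand <- if (prev < n) (prev + 1L):n else n
    # best match along the path coordinate, earliest sample on ties
    gap <- abs(snorm[cand] - points[q])
    best_k <- cand[which.min(gap)]
    # a query matching at (or a hair past) a true dwell — a run of exactly
    # repeated positions — is snapped back to the dwell start, the first
    # causal visit of that position; strictly monotone trajectories are
    # untouched
    same_pos <- function(k) {
      max(abs(traj$position[k - 1L, ] - traj$position[k, ])) < 1e-12
    }
    ds <- arc$sbar[2] - arc$sbar[1]
    j <- best_k
    while (j > prev + 1L && (snorm[best_k] - snorm[j]) <= ds) {
      if (same_pos(j)) {
        best_k <- j
        break
      }
      j <- j - 1L
    }
    while (best_k > prev + 1L && same_pos(best_k)) {
      best_k <- best_k - 1L
    }
    prev <- best_k
    out[q] <- traj$t[best_k]
  }
  out
}

#' Refine a movement onset or termination with the cubic
#' minimum-acceleration model
#'
#' Fits \eqn{x(t) = x_o} for \eqn{t \le t_o} and
#' \eqn{x(t) = x_o + \eta_m (t - t_o)^3 / 6} for
#' \eqn{t_o \le t \le t_o + \Delta T}
#' by grid search over candidate onsets within
#' `t_approx` ± `window`, with the closed-form least-squares solution for
#' \eqn{(x_o, \eta_m)} at each candidate. Termination detection reverses the
#' signal in time and runs the same fit.
#'
#' @param x scalar signal (e.g. hand displacement from the pre-onset rest
#'   position).
#' @param t timestamps (s), uniform.
#' @param t_approx approximate onset/termination time (s).
#' @param window half-width of the search window (s).
#' @param delta_T duration of the cubic segment included in the fit (s).
#' @param direction `"onset"` or `"termination"`.
#' @return list of class `onset_fit`: `x_o`, `eta_m` (signal units / s^3),
#'   `t_o` (s), `delta_T`, `rss`.
#' @export
refine_onset <- function(x, t, t_approx, window = 0.5, delta_T = 0.2,
                         direction = c("onset", "termination")) {
  direction <- match.arg(direction)
  stopifnot_contract(t_approx >= t[1] && t_approx <= t[length(t)],
                     "t_approx outside signal support")
  if (direction == "termination") {
    tr <- t[1] + (t[length(t)] - rev(t))
    fit <- refine_onset(rev(x), tr, t[1] + (t[length(t)] - t_approx),
                        window = window, delta_T = delta_T,
                        direction = "onset")
    fit$t_o <- t[1] + (t[length(t)] - fit$t_o)
    return(fit)
  }
  dt <- t[2] - t[1]
  in_win <- which(t >= t_approx - window & t <= t_approx + window)
  if (length(in_win) < 5 ||
      diff(range(x[in_win])) < 1e-12 * max(1, max(abs(x[in_win])))) {
    abort_aq("araquant_error_no_onset",
             "signal is flat within the onset search window")
  }
  # the fit support is fixed for all candidates and always extends into the
  # movement (cubic segment anchored at t1), so a candidate cannot "win" by
  # fitting only the static level; a second pass re-anchors t1 relative to
  # the first estimate
  fit_pass <- function(t1) {
    left <- max(t[1], t_approx - window - delta_T)
    sup <- which(t >= left & t <= t1)
    best <- NULL
    for (k in in_win) {
      t_o <- t[k]
      if (t_o > t1 - 3 * dt) next
      lo <- sup[t[sup] <= t_o]
      cub <- sup[t[sup] > t_o]
      if (length(cub) < 3 || length(lo) < 2) next
      g <- c(rep(0, length(lo)), (t[cub] - t_o)^3 / 6)
      A <- cbind(1, g)
      xs <- x[c(lo, cub)]
      coef <- tryCatch(qr.solve(A, xs), error = function(e) NULL)
      if (is.null(coef)) next
      rss <- sum((xs - A %*% coef)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(x_o = unname(coef[1]), eta_m = unname(coef[2]),
                     t_o = t_o, delta_T = t1 - t_o, rss = rss)
      }
    }
    best
  }
  t_end <- t[length(t)]
  # first pass anchors the cubic segment past the whole search window so the
  # movement is guaranteed to be inside the fitted support even when
  # t_approx errs early; later passes re-anchor at the running estimate
  # anchor the cubic segment where the signal has clearly departed from its
  # static level (so no candidate can fit flat data exactly, and the cubic
  # approximation of the early movement is still valid), then re-anchor once
  # relative to the estimate
  left0 <- max(t[1], t_approx - window - delta_T)
  reach <- which(t >= left0 & t <= min(t_end, t_approx + window + delta_T))
  # departure from the static level at the start of the analysis segment
  # (sign-agnostic: the signal may rise or fall away from rest)
  x_base <- stats::median(x[utils::head(reach, 5)])
  full_rng <- max(abs(x[reach] - x_base))
  crossing <- reach[which(abs(x[reach] - x_base) >= 0.15 * full_rng)[1]]
  t1_0 <- max(min(t_end, t[crossing]),
              t[min(length(t), which(t >= t_approx - window)[1] + 3L)])
  best <- fit_pass(t1_0)
  # progressively tighten the cubic support toward the estimate: the cubic
  # model is exact only in the earliest part of a bell-shaped movement
  for (shrink in c(1, 1, 0.5, 0.5, 0.25)) {
    if (is.null(best)) break
    t1_new <- min(t_end, best$t_o + shrink * delta_T)
    # tighten only while the support's rise stays clear of the static-region
    # noise floor; on flat or noise-dominated data every candidate fits the
    # static level equally well and the estimate would wander
    pre <- x[t >= left0 & t <= best$t_o]
    noise <- if (length(pre) > 2) stats::sd(pre) else 0
    rise <- diff(range(x[t >= best$t_o & t <= t1_new]))
    if (rise < max(5 * noise, 1e-9 * max(full_rng, 1e-12))) break
    best2 <- fit_pass(t1_new)
    if (!is.null(best2)) best <- best2
  }
  if (is.null(best)) {
    abort_aq("araquant_error_no_onset",
             "no admissible onset candidate in the search window")
  }
  class(best) <- "onset_fit"
  best
}
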