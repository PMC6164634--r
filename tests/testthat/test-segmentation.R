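straight_traj <- function(a, b, T = 2, fs = 100) {
  t <- seq(0, T, by = 1 / fs)
  pos <- outer(t / T, b - a) + matrix(a, length(t), 3, byrow = TRUE)
  time_trajectory(t, pos)
}

test_that("arc length of a constant-speed straight segment is the chord", {
  tr <- straight_traj(c(0, 0, 0), c(0.3, 0.4, 0))
  prof <- arc_length_profile(tr)
  expect_equal(prof$L, 0.5, tolerance = 1e-6)
  expect_true(all(diff(prof$s) >= 0))
  expect_equal(prof$s[1], 0)
})

test_that("arc length of a sampled circle matches the circumference", {
  r <- 0.25
  t <- seq(0, 2, length.out = 1000)
  pos <- cbind(r * cos(pi * t), r * sin(pi * t), 0)
  prof <- arc_length_profile(time_trajectory(t, pos))
  expect_lt(abs(prof$L - 2 * pi * r) / (2 * pi * r), 0.001)
})

test_that("stationary trajectories have zero length and cannot be arc-parameterized", {
  t <- seq(0, 1, by = 0.01)
  pos <- matrix(0.2, length(t), 3)
  expect_equal(arc_length_profile(time_trajectory(t, pos))$L, 0)
  expect_error(parameterize_by_arc(time_trajectory(t, pos)),
               class = "araquant_error_degenerate")
})

test_that("arc parameterization yields a uniform grid with origin-shifted start", {
  tr <- straight_traj(c(0.1, 0.2, -0.1), c(0.5, 0.2, -0.1))
  arc <- parameterize_by_arc(tr)
  expect_equal(arc$sbar[1], 0)
  expect_equal(arc$sbar[length(arc$sbar)], 1)
  expect_lt(diff(range(diff(arc$sbar))), 1e-12)
  expect_equal(arc$position[1, ], c(0, 0, 0))
  # constant-speed straight line: positions uniformly spaced along the line
  expect_lt(diff(range(diff(arc$position[, 1]))), 1e-6)
  # d(1) equals the start-end distance
  expect_equal(arc$distance[length(arc$sbar)], 0.4, tolerance = 1e-6)
})

test_that("mid-movement dwells collapse to a single arc point", {
  fs <- 100
  seg1 <- minimum_jerk_stroke(c(0, 0, 0), c(0.3, 0, 0), 1, fs)
  seg2 <- minimum_jerk_stroke(c(0.3, 0, 0), c(0.3, 0.3, 0), 1, fs)
  with_dwell <- function(dwell_s) {
    t_d <- if (dwell_s > 0) seq(1 / fs, dwell_s, by = 1 / fs) else numeric()
    t <- c(seg1$t, 1 + t_d, 1 + dwell_s + seg2$t[-1])
    dwell_rows <- if (length(t_d) > 0) {
      matrix(c(0.3, 0, 0), length(t_d), 3, byrow = TRUE)
    } else NULL
    pos <- rbind(seg1$position, dwell_rows, seg2$position[-1, ])
    parameterize_by_arc(time_trajectory(t, pos))
  }
  a0 <- with_dwell(0)
  a2 <- with_dwell(2)
  expect_equal(length(a0$sbar), length(a2$sbar))
  expect_lt(max(abs(a0$position - a2$position)), 1e-3)
})

test_that("direction change is zero on straight paths and peaks at corners", {
  tr <- straight_traj(c(0, 0, 0), c(0.4, 0, 0))
  arc <- parameterize_by_arc(tr)
  expect_lt(max(arc$nu), 1e-6)
  # right-angle corner
  t <- seq(0, 2, by = 0.01)
  pos <- cbind(pmin(t, 1) * 0.3, pmax(t - 1, 0) * 0.3, 0)
  arc <- parameterize_by_arc(time_trajectory(t, pos))
  expect_equal(max(arc$nu), pi / 2, tolerance = 0.05)
  expect_true(all(arc$nu >= 0 & arc$nu <= pi))
})

test_that("constant-curvature paths give constant direction change per step", {
  # planar semicircle: total turning pi spread over the grid
  t <- seq(0, 1, length.out = 2000)
  pos <- cbind(0.2 * cos(pi * t), 0.2 * sin(pi * t), 0)
  arc <- parameterize_by_arc(time_trajectory(t, pos))
  nin <- arc$nu[3:(length(arc$nu) - 2)]
  ds <- arc$sbar[2] - arc$sbar[1]
  expect_equal(stats::median(nin), pi * ds, tolerance = 0.02 * pi * ds)
  expect_lt(stats::sd(nin) / stats::median(nin), 0.05)
})

test_that("generator tasks are segmented with accurate boundaries", {
  rec <- generate_task(task_spec("grasp", 0.05), impairment_profile("H"),
                       seed = 5, streams = FALSE)
  arc <- parameterize_by_arc(time_trajectory(rec$truth$t,
                                             rec$truth$hand_position))
  seg <- segment_phases(arc, 3)
  mov <- seg$phases[seg$movement_phase_indices, ]
  expect_equal(nrow(mov), 3)
  expect_equal(mov$kind, c("reach_to_grasp", "transfer", "return"))
  tb <- rec$truth$phases
  expect_lt(max(abs(mov$sbar_term[1:2] - tb$sbar_term[1:2])), 0.02)
  # phases ordered and non-overlapping
  expect_true(all(mov$sbar_onset < mov$sbar_term))
  expect_true(all(diff(mov$t_onset) > 0))
  # manipulation phases sit between the movement phases
  manip <- seg$phases[seg$phases$kind %in% c("grasp", "release"), ]
  expect_equal(nrow(manip), 2)
  expect_true(all(manip$t_onset < manip$t_term))
})

test_that("a single stroke with expected count 1 spans the whole path", {
  tr <- minimum_jerk_stroke(c(0, 0, 0), c(0.4, 0.1, 0.2), 1.5)
  seg <- segment_phases(parameterize_by_arc(tr), 1)
  mov <- seg$phases[seg$movement_phase_indices, ]
  expect_equal(nrow(mov), 1)
  expect_equal(c(mov$sbar_onset, mov$sbar_term), c(0, 1))
})

test_that("too few boundary candidates raise a segmentation error with diagnostics", {
  tr <- minimum_jerk_stroke(c(0, 0, 0), c(0.4, 0, 0), 1.5)
  err <- tryCatch(segment_phases(parameterize_by_arc(tr), 3),
                  araquant_error_segmentation = function(e) e)
  expect_s3_class(err, "araquant_error_segmentation")
  expect_true(is.data.frame(err$data$candidates))
})

test_that("segmentation is invariant to uniform time re-scaling", {
  rec <- generate_task(task_spec("grasp", 0.05), impairment_profile("H"),
                       seed = 9, streams = FALSE)
  tr1 <- time_trajectory(rec$truth$t, rec$truth$hand_position)
  tr2 <- time_trajectory(rec$truth$t * 2.5, rec$truth$hand_position)
  b1 <- segment_phases(parameterize_by_arc(tr1), 3)
  b2 <- segment_phases(parameterize_by_arc(tr2), 3)
  m1 <- b1$phases[b1$movement_phase_indices, ]
  m2 <- b2$phases[b2$movement_phase_indices, ]
  expect_lt(max(abs(m1$sbar_term - m2$sbar_term)), 0.005)
})

test_that("arc-to-time matching inverts monotone arc length within a sample", {
  tr <- minimum_jerk_stroke(c(0, 0, 0), c(0.5, 0, 0), 2)
  arc <- parameterize_by_arc(tr)
  prof <- arc_length_profile(tr)
  pts <- c(0, 0.2, 0.5, 0.8, 1)
  got <- arc_to_time(arc, tr, pts)
  want <- approx(prof$s / prof$L, prof$t, xout = pts)$y
  expect_lt(max(abs(got - want)), 1.5 * (tr$t[2] - tr$t[1]))
  expect_equal(got[1], tr$t[1])
  expect_true(all(diff(got) > 0))
})

test_that("revisited positions match the first causally consistent visit", {
  # out to 0.4 and back to start: queries on the outbound leg must resolve
  # to outbound times and the output must stay strictly increasing
  s1 <- minimum_jerk_stroke(c(0, 0, 0), c(0.4, 0, 0), 1)
  s2 <- minimum_jerk_stroke(c(0.4, 0, 0), c(0, 0, 0), 1)
  t <- c(s1$t, 1 + s2$t[-1])
  tr <- time_trajectory(t, rbind(s1$position, s2$position[-1, ]))
  arc <- parameterize_by_arc(tr)
  got <- arc_to_time(arc, tr, c(0.1, 0.25, 0.4, 0.6, 0.9))
  expect_true(all(diff(got) > 0))
  expect_lt(got[2], 1)   # sbar 0.25 is on the outbound leg
  expect_gt(got[4], 1)   # sbar 0.6 is on the return leg
})

test_that("onset refinement recovers exact cubic onsets to the sample", {
  fs <- 100
  t <- seq(0, 4, by = 1 / fs)
  t_o <- 2.13
  x <- ifelse(t <= t_o, 0, (t - t_o)^3)  # x_o = 0, eta = 6
  fit <- refine_onset(x, t, 2.3, direction = "onset")
  expect_lte(abs(fit$t_o - t_o), 1 / fs)
  expect_equal(fit$eta_m, 6, tolerance = 0.01)
  expect_equal(fit$x_o, 0, tolerance = 1e-9)
})

test_that("onset refinement stays within two samples on minimum-jerk profiles", {
  fs <- 100
  t <- seq(0, 5, by = 1 / fs)
  on <- 1.5; T <- 1.2
  tau <- pmin(pmax((t - on) / T, 0), 1)
  x <- 0.4 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  fit <- refine_onset(x, t, on + 0.25, direction = "onset")
  expect_lte(abs(fit$t_o - on), 2 / fs)
  fit_t <- refine_onset(x, t, on + T - 0.15, direction = "termination")
  expect_lte(abs(fit_t$t_o - (on + T)), 2 / fs)
})

test_that("flat signals raise a no-onset error", {
  t <- seq(0, 4, by = 0.01)
  expect_error(refine_onset(rep(1, length(t)), t, 2),
               class = "araquant_error_no_onset")
})
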