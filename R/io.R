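#' Pipeline configuration
#'
#' All tunable defaults of the pipeline in one validated list. Every field
#' can be overridden by name; the configuration is echoed into the
#' provenance block of pipeline outputs.
#'
#' @param ... named overrides, e.g. `pipeline_config(dsbar = 0.001)`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    schema_version = 1L,
    fs = 100,                 # IMU sampling rate, Hz
    emg_fs = 200,             # EMG sampling rate, Hz
    dsbar = 1 / 500,          # normalized arc-length grid step
    zero_speed_frac = 0.02,   # arc-collapse speed threshold (fraction of peak)
    nu_prominence = pi / 6,   # direction-change peak prominence, rad
    boundary_window = 0.02,   # speed-min / nu-max coincidence window, sbar
    min_sep = 0.02,           # minimum boundary separation, sbar
    min_phase_frac = 0.05,    # minimum movement-phase extent, sbar
    speed_frac = 0.2,         # candidate speed ceiling (fraction of peak)
    onset_window = 0.5,       # onset grid-search half width, s
    onset_delta_T = 0.2,      # cubic fit segment length, s
    correction_gain = 0,      # drift-correction gain, 1/s
    alpha = 0.5,              # similarity weight, 1/m
    beta = 0.5,               # similarity weight, dimensionless
    theta_p = 1,              # jerk-index angular-displacement normalization
    jerk_cutoff_hz = 10,      # low-pass before double differentiation
    field_weight = 0.02,      # trunk complementary-filter blend weight
    max_gap_s = 0.05          # longest interpolatable sample gap, s
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  stopifnot_contract(length(unknown) == 0,
                     paste("unknown config fields:",
                           paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot_contract(fs > 0 && emg_fs > 0, "sampling rates must be > 0")
    stopifnot_contract(dsbar > 0 && dsbar <= 0.1, "dsbar out of range")
    stopifnot_contract(zero_speed_frac >= 0 && zero_speed_frac < 1,
                       "zero_speed_frac out of range")
    stopifnot_contract(alpha >= 0 && beta >= 0, "weights must be >= 0")
    stopifnot_contract(theta_p > 0, "theta_p must be > 0")
    stopifnot_contract(correction_gain >= 0, "gain must be >= 0")
  })
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write a synthetic recording to a directory
#'
#' Emits the on-disk dialect consumed by [read_recording()]: `imu.csv`
#' (long format, `t, sensor_id, gx..mz`, SI units), `emg.csv`
#' (`t, segment, e1..e8`; the `max_effort` segment holds the dynamometry
#' stand-in), `geometry.yaml` (handedness, segment lengths, calibration
#' posture) and `truth.json` (task descriptor, ground-truth phase table,
#' grasp-force level).
#'
#' @param rec a `synthetic_recording` with streams.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot_contract(inherits(rec, "synthetic_recording") &&
                       !is.null(rec$streams),
                     "rec must be a synthetic_recording with streams")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rec$streams$imu, file.path(dir, "imu.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$streams$emg, file.path(dir, "emg.csv"),
                   row.names = FALSE)
  geom <- list(
    handedness = rec$model$handedness,
    upper_arm_m = unname(rec$model$segment_lengths["upper_arm"]),
    forearm_m = unname(rec$model$segment_lengths["forearm"]),
    hand_m = unname(rec$model$segment_lengths["hand"]),
    initial_angles = as.numeric(rec$truth$initial_angles)
  )
  yaml::write_yaml(geom, file.path(dir, "geometry.yaml"))
  truth <- list(
    subtest = rec$task$subtest,
    object_size = rec$task$object_size,
    expected_movement_phases = rec$task$expected_movement_phases,
    group = rec$profile$group,
    seed = rec$seed,
    grasp_force = rec$truth$grasp_force,
    L = rec$truth$L,
    phases = rec$truth$phases
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

# interpolate short sample gaps in a numeric stream; returns filled data and
# the number of inserted samples
fill_gaps <- function(df, dt_nominal, max_gap_s) {
  t <- df$t
  dts <- diff(t)
  gap_at <- which(dts > 1.5 * dt_nominal)
  if (any(dts[gap_at] > max_gap_s)) {
    abort_aq("araquant_error_quality",
             sprintf("sample gap of %.3f s exceeds the %.3f s salvage limit",
                     max(dts[gap_at]), max_gap_s))
  }
  if (length(gap_at) == 0) return(list(df = df, inserted = 0L))
  grid <- seq(t[1], t[length(t)], by = dt_nominal)
  out <- data.frame(t = grid)
  for (col in setdiff(names(df), c("t", "sensor_id", "segment"))) {
    out[[col]] <- approx(t, df[[col]], xout = grid)$y
  }
  for (col in intersect(c("sensor_id", "segment"), names(df))) {
    out[[col]] <- df[[col]][1]
  }
  list(df = out[names(df)], inserted = nrow(out) - nrow(df))
}

#' Read and validate a recording bundle
#'
#' Loads the IMU CSV, EMG CSV, arm-geometry YAML and (when present) the
#' ground-truth JSON from a directory. Timestamps must be strictly
#' increasing per sensor; short sample gaps (at most `max_gap_s`) are filled
#' by linear interpolation and counted, longer gaps or more than 5% missing
#' samples raise a quality error; the EMG rate must be within 1% of
#' 200 Hz.
#'
#' @param dir recording directory, see [write_recording()].
#' @param arm which arm's sensors are required (`"right"` or `"left"`).
#' @param config a [pipeline_config()].
#' @return list of class `recording_bundle`: `imu` (list of per-sensor data
#'   frames), `emg`, `emg_max`, `model`, `initial_angles`, `truth` (or
#'   `NULL`), `gaps_filled`.
#' @export
read_recording <- function(dir, arm = c("right", "left"),
                           config = pipeline_config()) {
  arm <- match.arg(arm)
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      abort_aq("araquant_error_quality", paste("missing file:", f))
    }
    p
  }
  imu <- utils::read.csv(need("imu.csv"), stringsAsFactors = FALSE)
  emg <- utils::read.csv(need("emg.csv"), stringsAsFactors = FALSE)
  geom <- yaml::read_yaml(need("geometry.yaml"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  imu_cols <- c("t", "sensor_id", "gx", "gy", "gz", "ax", "ay", "az",
                "mx", "my", "mz")
  missing_cols <- setdiff(imu_cols, names(imu))
  if (length(missing_cols)) {
    abort_aq("araquant_error_parse",
             paste("imu.csv lacks column(s):",
                   paste(missing_cols, collapse = ", ")))
  }
  prefix <- if (arm == "right") "R_" else "L_"
  sensors <- c("trunk", paste0(prefix, c("upper", "wrist", "hand")))
  have <- unique(imu$sensor_id)
  if (!all(sensors %in% have)) {
    abort_aq("araquant_error_parse",
             paste("incomplete sensor set; missing:",
                   paste(setdiff(sensors, have), collapse = ", ")))
  }
  dt_nominal <- 1 / config$fs
  gaps <- 0L
  streams <- list()
  for (sid in sensors) {
    s <- imu[imu$sensor_id == sid, , drop = FALSE]
    if (any(diff(s$t) <= 0)) {
      abort_aq("araquant_error_parse",
               paste("non-monotone timestamps in sensor", sid))
    }
    filled <- fill_gaps(s, dt_nominal, config$max_gap_s)
    gaps <- gaps + filled$inserted
    streams[[sid]] <- filled$df
  }
  n_expected <- length(streams[[sensors[1]]]$t)
  if (gaps > 0.05 * n_expected * length(sensors)) {
    abort_aq("araquant_error_quality",
             sprintf("%d interpolated samples exceed the 5%% quality limit",
                     gaps))
  }
  stopifnot_contract(all(c("t", "segment") %in% names(emg)) &&
                       sum(grepl("^e[0-9]+$", names(emg))) == 8,
                     "emg.csv must have t, segment and e1..e8 columns")
  emg_task <- emg[emg$segment == "task", , drop = FALSE]
  emg_max <- emg[emg$segment == "max_effort", , drop = FALSE]
  emg_rate <- 1 / stats::median(diff(emg_task$t))
  if (abs(emg_rate - config$emg_fs) > 0.01 * config$emg_fs) {
    abort_aq("araquant_error_quality",
             sprintf("EMG rate %.1f Hz outside %g Hz +/- 1%%",
                     emg_rate, config$emg_fs))
  }
  model <- arm_model(handedness = geom$handedness,
                     upper_arm_m = geom$upper_arm_m,
                     forearm_m = geom$forearm_m, hand_m = geom$hand_m)
  if (gaps > 0) {
    message(sprintf("read_recording: %d missing samples interpolated", gaps))
  }
  structure(list(imu = streams, emg = emg_task, emg_max = emg_max,
                 model = model,
                 initial_angles = as.numeric(geom$initial_angles),
                 truth = truth, arm = arm, sensors = sensors,
                 gaps_filled = gaps),
            class = "recording_bundle")
}

#' Mirror an arc trajectory across the trunk sagittal plane
#'
#' Left-arm paths are mirrored (y -> -y in the trunk frame) before
#' comparison with a right-arm reference trajectory, so healthy left and
#' right executions can be pooled.
#'
#' @param arc an `arc_trajectory`.
#' @return the mirrored `arc_trajectory`.
#' @export
mirror_arc_trajectory <- function(arc) {
  arc$position[, 2] <- -arc$position[, 2]
  arc
}

#' Run the full quantification pipeline on a recording bundle
#'
#' Estimates trunk orientation and arm joint angles from the IMU streams,
#' computes the hand trajectory in the trunk frame by forward kinematics,
#' re-parameterizes it by normalized arc length, segments the task into
#' phases and computes the five quantification parameters per movement
#' phase and for the whole task. Deterministic given bundle and config.
#'
#' @param bundle a [read_recording()] bundle.
#' @param config a [pipeline_config()].
#' @param reference optional `reference_trajectory` for the similarity
#'   metrics (left `NULL`, `D`, `nu_hat` and `chi` are reported as `NA`).
#' @param expected_movement_phases overrides the phase count from the
#'   bundle's truth descriptor.
#' @return list of class `pipeline_result`: `metrics` (one row per movement
#'   phase plus a task row), `segmentation`, `arc`, `trunk`, `arm` (joint
#'   angle series), `provenance`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         reference = NULL,
                         expected_movement_phases = NULL) {
  stopifnot_contract(inherits(bundle, "recording_bundle"),
                     "bundle must come from read_recording()")
  m <- expected_movement_phases %||%
    bundle$truth$expected_movement_phases %||% 3
  trunk_stream <- bundle$imu$trunk
  trunk <- estimate_trunk_angles(trunk_stream,
                                 field_weight = config$field_weight)
  arm_ids <- setdiff(bundle$sensors, "trunk")
  omega <- do.call(cbind, lapply(arm_ids, function(sid)
    as.matrix(bundle$imu[[sid]][, c("gx", "gy", "gz")])))
  t <- bundle$imu[[arm_ids[1]]]$t
  est <- estimate_arm_motion(bundle$model, omega, t, bundle$initial_angles,
                             gain = config$correction_gain,
                             trunk_omega = as.matrix(
                               trunk_stream[, c("gx", "gy", "gz")]))
  hand <- t(apply(est$angles, 1, function(a)
    forward_kinematics(bundle$model, a)$position))
  traj <- time_trajectory(t, hand)
  arc <- parameterize_by_arc(traj, dsbar = config$dsbar,
                             zero_speed_frac = config$zero_speed_frac)
  if (bundle$model$handedness == "left") arc <- mirror_arc_trajectory(arc)
  seg <- segment_phases(arc, m,
                        nu_prominence = config$nu_prominence,
                        window = config$boundary_window,
                        min_sep = config$min_sep,
                        min_phase_frac = config$min_phase_frac,
                        speed_frac = config$speed_frac,
                        onset_window = config$onset_window,
                        onset_delta_T = config$onset_delta_T)
  hand_gyro <- as.matrix(
    bundle$imu[[grep("_hand$", arm_ids, value = TRUE)]][,
      c("gx", "gy", "gz")])
  w_max <- emg_rms(bundle$emg_max, min(bundle$emg_max$t),
                   max(bundle$emg_max$t))
  weights <- similarity_weights(config$alpha, config$beta)
  mov <- seg$phases[seg$movement_phase_indices, , drop = FALSE]
  one_row <- function(label, kind, t_on, t_tm, s_on, s_tm) {
    eta <- tryCatch(
      as.numeric(rotational_jerk_index(hand_gyro, t, t_on, t_tm,
                                       theta_p = config$theta_p,
                                       cutoff_hz = config$jerk_cutoff_hz)),
      araquant_error_contract = function(e) NA_real_)
    if (!is.null(reference)) {
      D <- euclidean_similarity(arc, reference, s_on, s_tm)
      nu <- direction_change_rms(arc, s_on, s_tm)
      chi <- trajectory_similarity(D, nu, weights)
    } else {
      D <- nu <- chi <- NA_real_
    }
    w_hat <- emg_rms(bundle$emg, t_on, t_tm)
    data.frame(phase = label, kind = kind, T_m = t_tm - t_on,
               eta_rot = eta, D = D, nu_hat = nu, chi = chi,
               rho = trunk_stability_index(trunk, t_on, t_tm),
               w_n = as.numeric(emg_normalize(w_hat, w_max)),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(mov)), function(i)
    one_row(as.character(mov$index[i]), mov$kind[i], mov$t_onset[i],
            mov$t_term[i],
            max(mov$sbar_onset[i], 0),
            min(mov$sbar_term[i], 1)))
  task_row <- one_row("task", "task", min(mov$t_onset), max(mov$t_term),
                      0, 1)
  metrics <- rbind(do.call(rbind, rows), task_row)
  # cheap deterministic fingerprint of the configuration
  cfg_str <- paste(names(config), format(unlist(config), digits = 15),
                   collapse = "|")
  cfg_codes <- utf8ToInt(cfg_str)
  structure(list(
    metrics = metrics, segmentation = seg, arc = arc, trunk = trunk,
    arm = est,
    provenance = list(
      package_version = as.character(utils::packageVersion("araquant")),
      config = unclass(config),
      config_hash = sprintf("%08x",
                            sum(cfg_codes * seq_along(cfg_codes)) %%
                              0xFFFFFFFF),
      gaps_filled = bundle$gaps_filled
    )
  ), class = "pipeline_result")
}

#' Write a segmentation to JSON
#'
#' One object per phase with `kind, sbar_onset, sbar_term, t_onset, t_term,
#' auto`.
#'
#' @param seg a `segmentation`.
#' @param path output file.
#' @export
write_segmentation <- function(seg, path) {
  jsonlite::write_json(
    seg$phases[, c("kind", "sbar_onset", "sbar_term", "t_onset", "t_term",
                   "auto")],
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
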