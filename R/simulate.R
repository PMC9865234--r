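# Synthetic cohort generator: forward-kinematic two-IMU wrist model.
#
# Emulates a bench-top occupational study: P participants x 2 sessions x
# 2 repetitions x 3 tasks, recorded at 100 Hz, with ground-truth wrist angles
# (flexion/extension, radial/ulnar deviation, pronation/supination) and the
# 12-channel inertial stream of a hand sensor and a wrist sensor.

WP_TASKS <- c("assembly", "checkout", "typing")
WP_IMU_CHANNELS <- c("hacc_x", "hacc_y", "hacc_z", "hgyr_x", "hgyr_y", "hgyr_z",
                     "wacc_x", "wacc_y", "wacc_z", "wgyr_x", "wgyr_y", "wgyr_z")

#' Per-task wrist-motion profiles
#'
#' Dwell/excursion parameters controlling the marginal angle distributions of
#' each simulated task. Each profile holds, per angular channel, a mean and SD
#' in degrees (the task-dwell posture and its spread), a band limit in Hz for
#' the underlying smooth random motion, and a Poisson rate (events per second)
#' plus peak-amplitude range for rare high-flexion excursions.
#'
#' The dispersions are calibrated so the pooled windowed FE labels of a
#' default cohort place roughly 90% of their mass in the two dominant central
#' bins, matching the strong neutral-posture concentration typical of bench
#' work, with high-flexion windows rare.
#'
#' @return Named list of task profiles.
#' @export
default_task_mixture <- function() {
  list(
    assembly = list(fe_mean = -10, fe_sd = 20, ru_mean = 0,  ru_sd = 9,
                    ps_mean = 10,  ps_sd = 25, band_hz = 1.5,
                    excursion_rate = 0.008, excursion_peak = c(55, 85)),
    checkout = list(fe_mean = -12, fe_sd = 18, ru_mean = -3, ru_sd = 8,
                    ps_mean = 0,   ps_sd = 30, band_hz = 1.2,
                    excursion_rate = 0.006, excursion_peak = c(55, 85)),
    typing   = list(fe_mean = -18, fe_sd = 10, ru_mean = 3,  ru_sd = 6,
                    ps_mean = -60, ps_sd = 8,  band_hz = 1.0,
                    excursion_rate = 0.001, excursion_peak = c(50, 70))
  )
}

#' Simulation configuration
#'
#' @param seed Integer master seed; the whole cohort is a pure function of
#'   `(n_participants, config)`.
#' @param duration_s Named numeric vector of recording durations in seconds,
#'   one per task (sweeps included). Defaults give roughly 30 min of data per
#'   participant across their 12 recordings.
#' @param gravity_g Gravitational acceleration, m/s^2.
#' @param gyro_noise_sd Gyroscope white-noise SD, deg/s.
#' @param acc_noise_sd Accelerometer white-noise SD, m/s^2.
#' @param misalignment_sd SD (degrees, per Euler axis) of the fixed
#'   sensor-mount rotation drawn once per participant per sensor; emulates
#'   approximate visual sensor placement with no alignment calibration.
#' @param task_mixture Per-task dwell/excursion profiles, see
#'   [default_task_mixture()].
#' @param sweep_s Duration (seconds) of the scripted range-of-motion sweep
#'   performed at the start and again at the end of every recording.
#' @param forearm_walk_deg Amplitude (degrees, SD per axis) of the slow
#'   forearm-orientation random walk emulating standing bench work; 0 holds
#'   the forearm stationary.
#' @param forearm_drift_m Amplitude (metres, SD per axis) of the slow elbow
#'   position drift feeding the linear-acceleration term; 0 disables it.
#' @param fs Sampling rate, Hz.
#' @param fe_sign,ru_sign `+1` or `-1`; sign convention flips. The defaults
#'   take flexion positive and radial deviation positive.
#' @return An object of class `wp_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = c(assembly = 150, checkout = 130, typing = 180),
                       gravity_g = 9.81,
                       gyro_noise_sd = 0.5,
                       acc_noise_sd = 0.05,
                       misalignment_sd = 5,
                       task_mixture = default_task_mixture(),
                       sweep_s = 6,
                       forearm_walk_deg = 8,
                       forearm_drift_m = 0.03,
                       fs = 100,
                       fe_sign = 1,
                       ru_sign = 1) {
  stopifnot(all(WP_TASKS %in% names(duration_s)),
            all(duration_s > 1),
            fs > 0, gravity_g > 0, sweep_s >= 0,
            fe_sign %in% c(-1, 1), ru_sign %in% c(-1, 1))
  cfg <- list(seed = as.integer(seed), duration_s = duration_s,
              gravity_g = gravity_g, gyro_noise_sd = gyro_noise_sd,
              acc_noise_sd = acc_noise_sd, misalignment_sd = misalignment_sd,
              task_mixture = task_mixture, sweep_s = sweep_s,
              forearm_walk_deg = forearm_walk_deg,
              forearm_drift_m = forearm_drift_m, fs = fs,
              fe_sign = fe_sign, ru_sign = ru_sign)
  class(cfg) <- "wp_sim_config"
  cfg
}

# Scripted range-of-motion sweep: sequential full-cycle excursions in FE,
# RU, then PS, each over a third of the sweep window.
rom_sweep <- function(n, fs) {
  out <- matrix(0, n, 3, dimnames = list(NULL, c("fe", "ru", "ps")))
  if (n < 3L) return(out)
  third <- floor(n / 3)
  segs <- list(1:third, (third + 1):(2 * third), (2 * third + 1):n)
  amps <- c(fe = 60, ru = 28, ps = 80)
  for (k in 1:3) {
    idx <- segs[[k]]
    ph <- seq(0, 2 * pi, length.out = length(idx))
    out[idx, k] <- amps[k] * sin(ph)
  }
  out
}

#' Simulate a ground-truth wrist angle trajectory
#'
#' Produces one recording's worth of smooth (band-limited, < 5 Hz) FE/RU/PS
#' angle traces for a named task: a scripted range-of-motion sweep at the
#' start, task-specific dwell motion around a near-neutral posture with rare
#' high-flexion excursions, and a closing sweep. Angles are clamped to
#' physiological ranges (|FE| <= 90, |RU| <= 45, |PS| <= 100 degrees).
#'
#' @param task One of `"assembly"`, `"checkout"`, `"typing"`.
#' @param duration_s Recording duration in seconds (> 1), sweeps included.
#' @param config A [sim_config()].
#' @param seed Integer seed for this trajectory.
#' @return A `data.frame` with columns `t` (sample index, 100 Hz),
#'   `theta_fe`, `theta_ru`, `theta_ps` (degrees).
#' @export
simulate_angle_trajectory <- function(task, duration_s, config = sim_config(),
                                      seed = config$seed) {
  if (!task %in% names(config$task_mixture)) {
    stop("unknown task '", task, "'; configured tasks: ",
         paste(names(config$task_mixture), collapse = ", "))
  }
  stopifnot(duration_s > 1)
  fs <- config$fs
  n <- round(duration_s * fs)
  prof <- config$task_mixture[[task]]

  with_seed(seed, {
    chan <- function(mean, sd) {
      if (sd <= 0) rep(mean, n)
      else mean + sd * bandlimited_noise(n, fs, prof$band_hz)
    }
    fe <- chan(prof$fe_mean, prof$fe_sd)
    ru <- chan(prof$ru_mean, prof$ru_sd)
    ps <- chan(prof$ps_mean, prof$ps_sd)

    # Rare scripted excursions into high flexion (raised-Gaussian bumps).
    rate <- prof$excursion_rate %||% 0
    if (rate > 0) {
      n_ev <- stats::rpois(1, rate * duration_s)
      if (n_ev > 0) {
        t_idx <- seq_len(n) / fs
        for (i in seq_len(n_ev)) {
          t0 <- stats::runif(1, 0, duration_s)
          peak <- stats::runif(1, prof$excursion_peak[1], prof$excursion_peak[2])
          fe <- fe + (peak - prof$fe_mean) * exp(-(t_idx - t0)^2 / (2 * 0.35^2))
        }
      }
    }

    # Range-of-motion sweeps at both ends, cross-faded over 0.5 s so the
    # assembled trace stays smooth.
    n_sw <- round(config$sweep_s * fs)
    if (n_sw > 0 && 2L * n_sw < n) {
      sw <- rom_sweep(n_sw, fs)
      # weight for task motion: 0 during sweeps, ramping at the joints
      w <- rep(1, n)
      w[1:n_sw] <- 0
      w[(n - n_sw + 1):n] <- 0
      ramp <- seq(0, 1, length.out = round(0.5 * fs))
      j1 <- n_sw + seq_along(ramp)
      j2 <- n - n_sw + 1 - rev(seq_along(ramp))
      w[j1[j1 <= n]] <- ramp[j1 <= n]
      w[j2[j2 >= 1]] <- rev(ramp)[j2 >= 1]
      sweep_fe <- c(sw[, "fe"], rep(0, n - 2L * n_sw), sw[, "fe"])
      sweep_ru <- c(sw[, "ru"], rep(0, n - 2L * n_sw), sw[, "ru"])
      sweep_ps <- c(sw[, "ps"], rep(0, n - 2L * n_sw), sw[, "ps"])
      fe <- w * fe + (1 - w) * sweep_fe
      ru <- w * ru + (1 - w) * sweep_ru
      ps <- w * ps + (1 - w) * sweep_ps
    }

    data.frame(
      t = seq_len(n) - 1L,
      theta_fe = pmax(-90, pmin(90, config$fe_sign * fe)),
      theta_ru = pmax(-45, pmin(45, config$ru_sign * ru)),
      theta_ps = pmax(-100, pmin(100, ps))
    )
  })
}

# Fixed mount rotation for one sensor: small XYZ Euler rotation with
# per-axis SD `sd_deg`. Consumes the caller's RNG stream.
draw_misalignment <- function(sd_deg) {
  a <- stats::rnorm(3, 0, sd_deg) * pi / 180
  rot_matrix_xyz(a[1], a[2], a[3])
}

#' Forward sensor model: angles to 12-channel inertial stream
#'
#' Maps a ground-truth angle trace through a rigid-body model of the forearm
#' and hand to the signals of two body-worn 6-DOF IMUs. The forearm follows a
#' slow random walk in orientation and position (standing bench work); the
#' hand segment is the forearm orientation composed with rotations by PS, FE
#' and RU about the anatomical axes. Gyroscope channels are the segment
#' angular velocity expressed in the (possibly misaligned) sensor frame;
#' accelerometer channels are specific force: gravity plus segment linear
#' acceleration, expressed in the sensor frame, plus white noise.
#'
#' @param angles An angle trace as returned by [simulate_angle_trajectory()].
#' @param config A [sim_config()].
#' @param seed Integer seed (forearm walk + sensor noise).
#' @param misalign Optional list with 3x3 rotation matrices `hand` and
#'   `wrist` (sensor mount relative to segment). `NULL` means perfectly
#'   aligned sensors.
#' @return Numeric matrix with one row per sample and the 12 columns
#'   `hacc_x..z, hgyr_x..z, wacc_x..z, wgyr_x..z` (m/s^2 and deg/s).
#' @export
forward_model <- function(angles, config = sim_config(), seed = config$seed,
                          misalign = NULL) {
  stopifnot(is.data.frame(angles),
            all(c("theta_fe", "theta_ru", "theta_ps") %in% names(angles)))
  n <- nrow(angles)
  stopifnot(n > 2)
  fs <- config$fs
  deg <- pi / 180

  with_seed(seed, {
    # Forearm orientation: slow, small-amplitude random walk about a bench
    # posture (forearm roughly horizontal, pointing ahead).
    walk <- function(amp_deg, hz = 0.3) {
      if (amp_deg <= 0) rep(0, n) else amp_deg * deg * bandlimited_noise(n, fs, hz)
    }
    amp <- config$forearm_walk_deg %||% 8
    r_fore <- rot_mult(rot_z(walk(1.25 * amp)),
                       rot_mult(rot_y(walk(amp)), rot_x(walk(amp))))

    # Hand orientation: forearm composed with PS about the distal x-axis,
    # FE about the radial y-axis (flexion positive) and RU about the dorsal
    # z-axis (radial deviation positive).
    r_hand <- rot_mult(
      r_fore,
      rot_mult(rot_x(angles$theta_ps * deg),
               rot_mult(rot_y(angles$theta_fe * deg),
                        rot_z(angles$theta_ru * deg))))

    # Segment angular velocities in their own frames, deg/s.
    w_hand <- rot_to_angular_velocity(r_hand, fs)
    w_fore <- rot_to_angular_velocity(r_fore, fs)

    # Sensor positions from a simple articulated chain: elbow point drifting
    # slowly in space, wrist sensor on the distal forearm, hand sensor on the
    # dorsum of the hand.
    drift_amp <- config$forearm_drift_m %||% 0.03
    drift <- function() {
      if (drift_amp <= 0) rep(0, n) else drift_amp * bandlimited_noise(n, fs, 0.5)
    }
    ex <- drift(); ey <- drift(); ez <- drift()
    off_w <- rot_apply(r_fore, 0.22, 0, 0.02)
    off_h0 <- rot_apply(r_fore, 0.25, 0, 0)
    off_h <- rot_apply(r_hand, 0.05, 0, 0.015)
    p_ws <- list(x = ex + off_w$x, y = ey + off_w$y, z = ez + off_w$z)
    p_hs <- list(x = ex + off_h0$x + off_h$x,
                 y = ey + off_h0$y + off_h$y,
                 z = ez + off_h0$z + off_h$z)

    lin_acc <- function(p) {
      dt <- 1 / fs
      lapply(p, function(x) central_diff(central_diff(x, dt), dt))
    }
    a_ws <- lin_acc(p_ws)
    a_hs <- lin_acc(p_hs)

    g <- config$gravity_g
    f_hand <- rot_apply_t(r_hand, a_hs$x, a_hs$y, a_hs$z + g)
    f_wrist <- rot_apply_t(r_fore, a_ws$x, a_ws$y, a_ws$z + g)

    sensor_block <- function(f, w, m) {
      acc <- cbind(f$x, f$y, f$z)
      gyr <- cbind(w$x, w$y, w$z) / deg
      if (!is.null(m)) {
        acc <- acc %*% m        # (M^T a^T)^T = a M
        gyr <- gyr %*% m
      }
      acc <- acc + matrix(stats::rnorm(3 * n, 0, config$acc_noise_sd), n, 3)
      gyr <- gyr + matrix(stats::rnorm(3 * n, 0, config$gyro_noise_sd), n, 3)
      cbind(acc, gyr)
    }

    imu <- cbind(sensor_block(f_hand, w_hand, misalign$hand),
                 sensor_block(f_wrist, w_fore, misalign$wrist))
    colnames(imu) <- WP_IMU_CHANNELS
    imu
  })
}

#' Generate a synthetic cohort of paired angle/IMU recordings
#'
#' Enumerates the full study design — `n_participants` x 2 sessions x
#' 2 repetitions x 3 tasks — and simulates every recording. Each
#' participant's two sensor-mount misalignments are drawn once and held fixed
#' across all of that participant's recordings. The cohort is a pure function
#' of `(n_participants, config)`: the same inputs reproduce it bit for bit.
#'
#' @param n_participants Number of participants (>= 1).
#' @param config A [sim_config()].
#' @return An object of class `wp_cohort`: a list of recordings, each a list
#'   with elements `meta` (participant, session, repetition, task), `angles`,
#'   `imu`, `sweep_samples` and `fs`. The simulation config is attached as
#'   attribute `config`.
#' @export
generate_cohort <- function(n_participants, config = sim_config()) {
  stopifnot(n_participants >= 1)
  recs <- list()
  for (p in seq_len(n_participants)) {
    mis <- with_seed(derive_seed(config$seed, "misalign", p), list(
      hand = draw_misalignment(config$misalignment_sd),
      wrist = draw_misalignment(config$misalignment_sd)
    ))
    for (s in 1:2) for (r in 1:2) for (task in WP_TASKS) {
      sd_traj <- derive_seed(config$seed, "traj", p, s, r, task)
      sd_imu <- derive_seed(config$seed, "imu", p, s, r, task)
      ang <- simulate_angle_trajectory(task, config$duration_s[[task]],
                                       config, seed = sd_traj)
      imu <- forward_model(ang, config, seed = sd_imu, misalign = mis)
      recs[[length(recs) + 1L]] <- structure(list(
        meta = list(participant = p, session = s, repetition = r, task = task),
        angles = ang,
        imu = imu,
        sweep_samples = round(config$sweep_s * config$fs),
        fs = config$fs
      ), class = "wp_recording")
    }
  }
  structure(recs, class = "wp_cohort", config = config)
}

#' @export
print.wp_cohort <- function(x, ...) {
  p <- unique(vapply(x, function(r) r$meta$participant, 0))
  cat("<wp_cohort> ", length(x), " recordings, ", length(p),
      " participants\n", sep = "")
  invisible(x)
}

recording_filename <- function(meta) {
  sprintf("P%02d_S%d_R%d_%s.csv", meta$participant, meta$session,
          meta$repetition, meta$task)
}

#' Write a cohort to disk as per-recording CSV files plus a JSON manifest
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("output directory '", dir, "' is not empty; use force = TRUE")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(cohort, "config")
  files <- character(0)
  for (rec in cohort) {
    fn <- recording_filename(rec$meta)
    df <- cbind(rec$angles, as.data.frame(rec$imu))
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
    files <- c(files, fn)
  }
  manifest <- list(
    config_hash = config_hash(unclass(cfg)),
    n_recordings = length(cohort),
    fs = cfg$fs,
    sweep_samples = round(cfg$sweep_s * cfg$fs),
    files = files,
    meta = lapply(cohort, function(r) r$meta)
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir Directory containing the recording CSVs and `manifest.json`.
#' @return A `wp_cohort` (without the original simulation config).
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in '", dir, "'")
  manifest <- jsonlite::read_json(mp, simplifyVector = FALSE)
  recs <- lapply(seq_along(manifest$files), function(i) {
    df <- utils::read.csv(file.path(dir, manifest$files[[i]]))
    meta <- manifest$meta[[i]]
    structure(list(
      meta = list(participant = meta$participant, session = meta$session,
                  repetition = meta$repetition, task = meta$task),
      angles = df[c("t", "theta_fe", "theta_ru", "theta_ps")],
      imu = as.matrix(df[WP_IMU_CHANNELS]),
      sweep_samples = manifest$sweep_samples,
      fs = manifest$fs
    ), class = "wp_recording")
  })
  structure(recs, class = "wp_cohort", manifest_hash = manifest$config_hash)
}
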