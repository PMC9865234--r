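# Forward-kinematic synthetic cohort generator.

test_that("angle trajectories have the right length, limits and smoothness", {
  cfg <- tiny_sim_config()
  ang <- simulate_angle_trajectory("assembly", 60, cfg, seed = 3)
  expect_equal(nrow(ang), 6000)
  expect_true(all(abs(ang$theta_fe) <= 90))
  expect_true(all(abs(ang$theta_ru) <= 45))
  expect_true(all(abs(ang$theta_ps) <= 100))
  # band-limited: negligible spectral mass above 5 Hz
  sp <- stats::spec.pgram(ang$theta_fe - mean(ang$theta_fe), plot = FALSE,
                          taper = 0)
  hi <- sp$freq * cfg$fs > 5
  expect_lt(sum(sp$spec[hi]) / sum(sp$spec), 0.01)
})

test_that("unknown task names are a configuration error", {
  expect_error(simulate_angle_trajectory("welding", 10, tiny_sim_config()),
               "unknown task")
})

test_that("a constant neutral dwell profile with no excursions is identically zero", {
  cfg <- tiny_sim_config()
  cfg$sweep_s <- 0
  cfg$task_mixture$assembly[c("fe_mean", "fe_sd", "ru_mean", "ru_sd",
                              "ps_mean", "ps_sd", "excursion_rate")] <-
    list(0, 0, 0, 0, 0, 0, 0)
  ang <- simulate_angle_trajectory("assembly", 10, cfg, seed = 5)
  expect_true(all(ang$theta_fe == 0))
  expect_true(all(ang$theta_ru == 0))
  expect_true(all(ang$theta_ps == 0))
})

test_that("a static posture yields zero gyro and exactly 1 g on each accelerometer", {
  cfg <- sim_config(seed = 1, gyro_noise_sd = 0, acc_noise_sd = 0,
                    misalignment_sd = 0, forearm_walk_deg = 0,
                    forearm_drift_m = 0)
  ang <- data.frame(t = 0:499, theta_fe = 20, theta_ru = -5, theta_ps = 30)
  imu <- forward_model(ang, cfg, seed = 5)
  gyro_cols <- c(4:6, 10:12)
  expect_equal(max(abs(imu[, gyro_cols])), 0)
  expect_equal(sqrt(rowSums(imu[, 1:3]^2)), rep(9.81, 500), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(imu[, 7:9]^2)), rep(9.81, 500), tolerance = 1e-9)
})

test_that("a constant-rate flexion ramp appears on the hand gyro FE axis", {
  # rigid-body oracle: rotation about a single fixed axis at 30 deg/s puts
  # exactly 30 deg/s on that body axis and zero elsewhere
  cfg <- sim_config(seed = 1, gyro_noise_sd = 0, acc_noise_sd = 0,
                    misalignment_sd = 0, forearm_walk_deg = 0,
                    forearm_drift_m = 0)
  n <- 400
  ang <- data.frame(t = seq_len(n) - 1L, theta_fe = 30 * seq_len(n) / 100,
                    theta_ru = 0, theta_ps = 0)
  imu <- forward_model(ang, cfg, seed = 6)
  mid <- 50:350  # away from the one-sided finite differences at the ends
  expect_equal(unname(imu[mid, "hgyr_y"]), rep(30, length(mid)),
               tolerance = 1e-4)
  expect_lt(max(abs(imu[mid, c("hgyr_x", "hgyr_z")])), 1e-4)
  # wrist (forearm) sensor sees no rotation
  expect_lt(max(abs(imu[mid, c("wgyr_x", "wgyr_y", "wgyr_z")])), 1e-6)
})

test_that("numerical differentiation of simulated orientation recovers gyro rates", {
  # kinematic consistency on a noise-free multi-axis motion: integrate the
  # reported hand gyro back and compare against the reference FE ramp + RU sine
  cfg <- sim_config(seed = 1, gyro_noise_sd = 0, acc_noise_sd = 0,
                    misalignment_sd = 0, forearm_walk_deg = 0,
                    forearm_drift_m = 0)
  n <- 500
  t <- seq_len(n) / 100
  ang <- data.frame(t = seq_len(n) - 1L, theta_fe = 10 * sin(2 * pi * 0.5 * t),
                    theta_ru = 0, theta_ps = 0)
  imu <- forward_model(ang, cfg, seed = 2)
  # single-axis motion: gyro y should equal the analytic derivative of FE
  expected <- 10 * 2 * pi * 0.5 * cos(2 * pi * 0.5 * t)
  mid <- 25:475
  expect_equal(unname(imu[mid, "hgyr_y"]), expected[mid], tolerance = 1e-2)
})

test_that("the cohort enumerates the full design and is seed-reproducible", {
  cfg <- tiny_sim_config(duration = 5)
  one <- generate_cohort(1, cfg)
  expect_length(one, 12)
  metas <- unique(t(sapply(one, function(r) unlist(r$meta[c("session",
                                                            "repetition",
                                                            "task")]))))
  expect_equal(nrow(metas), 12)  # all session x repetition x task distinct

  again <- generate_cohort(1, cfg)
  expect_identical(one[[5]]$imu, again[[5]]$imu)
  expect_identical(one[[5]]$angles, again[[5]]$angles)

  other <- generate_cohort(1, tiny_sim_config(seed = 43, duration = 5))
  expect_false(identical(one[[5]]$imu, other[[5]]$imu))
})

test_that("cohort CSV round trip preserves recordings and the manifest is deterministic", {
  cfg <- tiny_sim_config(duration = 3)
  cohort <- generate_cohort(1, cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(cohort, d1, force = TRUE)
  write_cohort(cohort, d2, force = TRUE)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  back <- read_cohort(d1)
  expect_length(back, 12)
  expect_equal(back[[3]]$imu, cohort[[3]]$imu, tolerance = 1e-6)
  expect_equal(back[[3]]$meta, cohort[[3]]$meta)
})
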