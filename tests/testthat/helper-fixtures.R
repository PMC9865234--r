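# Shared fixtures, all generated in code at test time.

# Small low-noise simulation config for fast unit tests.
tiny_sim_config <- function(seed = 42, duration = 20, noise = TRUE) {
  sim_config(
    seed = seed,
    duration_s = c(assembly = duration, checkout = duration, typing = duration),
    gyro_noise_sd = if (noise) 0.5 else 0,
    acc_noise_sd = if (noise) 0.05 else 0,
    misalignment_sd = if (noise) 5 else 0,
    sweep_s = 3
  )
}

# A hand-built recording with prescribed constant angles and synthetic IMU
# signal, bypassing the simulator (for windowing/label tests).
constant_recording <- function(n = 400, fe = 0, ru = 0, ps = 0,
                               participant = 1, session = 1, repetition = 1,
                               task = "assembly", fs = 100) {
  structure(list(
    meta = list(participant = participant, session = session,
                repetition = repetition, task = task),
    angles = data.frame(t = seq_len(n) - 1L, theta_fe = rep(fe, n),
                        theta_ru = rep(ru, n), theta_ps = rep(ps, n)),
    imu = matrix(stats::rnorm(n * 12), n, 12,
                 dimnames = list(NULL, wristposture:::WP_IMU_CHANNELS)),
    sweep_samples = 0L,
    fs = fs
  ), class = "wp_recording")
}

# Windows with prescribed target angles (x blocks are noise); used for the
# resampling tests where only labels matter.
labelled_windows <- function(mean_fe, mean_ru = rep(0, length(mean_fe)),
                             participant = 1, session = 1, repetition = 1,
                             task = "assembly", with_x = FALSE) {
  n <- length(mean_fe)
  x <- if (with_x) matrix(stats::runif(n * 1200), n, 1200) else NULL
  wristposture:::new_windows(
    x, mean_fe, mean_ru,
    data.frame(participant = participant, session = session,
               repetition = repetition, task = task,
               start_index = seq_len(n) - 1L))
}

# Two well-separated window prototypes with labels in different FE bins:
# a linearly separable toy problem for the training sanity checks.
separable_toy_windows <- function(n = 240, seed = 7) {
  set.seed(seed)
  proto <- list(matrix(stats::runif(1200), 1, 1200),
                matrix(stats::runif(1200), 1, 1200))
  fe <- c(0, -30)   # bins 2 and 3
  cls <- rep(1:2, each = n / 2)
  x <- do.call(rbind, lapply(cls, function(k) {
    pmin(pmax(proto[[k]] + stats::rnorm(1200, 0, 0.02), 0), 1)
  }))
  wristposture:::new_windows(
    x, mean_fe = fe[cls], mean_ru = rep(0, n),
    meta = data.frame(participant = 1, session = 1, repetition = 1,
                      task = "assembly", start_index = seq_len(n) - 1L))
}
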