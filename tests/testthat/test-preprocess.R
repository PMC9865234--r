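# Filtering, normalization, windowing, and posture binning.

test_that("zero-lag filter passes DC, attenuates far above cutoff, adds no lag", {
  fs <- 100
  t <- seq_len(1000) / fs
  expect_equal(zero_lag_lowpass(rep(3.7, 1000), 5, fs), rep(3.7, 1000),
               tolerance = 1e-6)

  # 20 Hz tone vs 5 Hz cutoff: squared 4th-order Butterworth magnitude at
  # 4x cutoff is (1 + 4^8)^-1, far below the 5% amplitude bound
  x20 <- sin(2 * pi * 20 * t)
  y20 <- zero_lag_lowpass(x20, 5, fs)
  mid <- 200:800
  expect_lt(max(abs(y20[mid])), 0.05)

  # zero-phase: cross-correlation of a passband tone peaks at lag 0
  x1 <- sin(2 * pi * 1 * t)
  y1 <- zero_lag_lowpass(x1, 5, fs)
  cc <- stats::ccf(y1[mid], x1[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_equal(y1[mid], x1[mid], tolerance = 1e-2)
})

test_that("too-short signals produce an explicit error naming the minimum length", {
  expect_error(zero_lag_lowpass(rnorm(20), 5, 100, order = 4), "27")
})

test_that("min/max normalization maps endpoints, clips held-out extremes, zeroes degenerate channels", {
  rec <- constant_recording(n = 50)
  rec$imu[, 1] <- seq(-3, 5, length.out = 50)
  rec$imu[, 2] <- 2  # degenerate
  params <- fit_normalization(list(rec))
  expect_equal(unname(params$min[1]), -3)
  expect_equal(unname(params$max[1]), 5)

  held <- rec$imu
  held[1, 1] <- 7    # beyond training max
  held[2, 1] <- -10  # beyond training min
  expect_warning(norm <- apply_normalization(held, params), "degenerate")
  expect_equal(unname(norm[1, 1]), 1)
  expect_equal(unname(norm[2, 1]), 0)
  expect_true(all(norm >= 0 & norm <= 1))
  expect_true(all(norm[, 2] == 0))
  expect_equal(unname(norm[50, 1]), 1)   # train max -> 1
  # train min value -3 sits at row 1 pre-overwrite; check an interior point
  expect_equal(unname(norm[25, 1]), unname(held[25, 1] + 3) / 8,
               tolerance = 1e-12)
})

test_that("window counts follow the stride formula and match brute-force enumeration", {
  rec <- constant_recording(n = 100)
  expect_equal(n_windows(make_windows(rec)), 1)
  rec <- constant_recording(n = 200)
  expect_equal(n_windows(make_windows(rec)), 11)

  for (n in c(100, 101, 109, 110, 345, 777, 1000)) {
    rec <- constant_recording(n = n)
    brute <- sum(sapply(0:(n - 100), function(s) s %% 10 == 0))
    expect_equal(n_windows(make_windows(rec)), brute)
    expect_equal(n_windows(make_windows(rec)), floor((n - 100) / 10) + 1)
  }

  # each additional full second of signal adds 10 windows
  n1 <- n_windows(make_windows(constant_recording(n = 500)))
  n2 <- n_windows(make_windows(constant_recording(n = 600)))
  expect_equal(n2 - n1, 10)
})

test_that("recordings shorter than one window yield an empty set with a warning", {
  expect_warning(w <- make_windows(constant_recording(n = 50)), "shorter")
  expect_equal(n_windows(w), 0)
})

test_that("window labels are the central-10-sample mean and bins match the label", {
  rec <- constant_recording(n = 300, fe = -20, ru = 12)
  w <- make_windows(rec)
  expect_equal(w$mean_fe, rep(-20, n_windows(w)))
  expect_equal(w$fe_bin, rep(bin_fe(-20), n_windows(w)))
  expect_equal(w$ru_bin, rep(bin_ru(12), n_windows(w)))

  # a linear FE ramp: central mean is the angle at the window center
  rec <- constant_recording(n = 200)
  rec$angles$theta_fe <- seq_len(200)  # 1..200 by sample
  w <- make_windows(rec)
  # window starting at offset s (0-based) covers samples s+1..s+100 with
  # central samples s+46..s+55 whose mean is s + 50.5
  expect_equal(w$mean_fe, w$meta$start_index + 50.5)
})

test_that("window x blocks are the channel-major flattening of the 12x100 slice", {
  rec <- constant_recording(n = 150)
  w <- make_windows(rec)
  s <- w$meta$start_index[2]
  block <- t(rec$imu[(s + 1):(s + 100), ])
  expect_equal(w$x[2, ], as.vector(block))
})

test_that("range-of-motion sweeps can be excluded from windowing", {
  rec <- constant_recording(n = 600)
  rec$sweep_samples <- 200L
  w_all <- make_windows(rec, include_rom_sweeps = TRUE)
  w_task <- make_windows(rec, include_rom_sweeps = FALSE)
  expect_gt(n_windows(w_all), n_windows(w_task))
  expect_true(all(w_task$meta$start_index >= 200))
  expect_true(all(w_task$meta$start_index + 100 <= 400))
})

test_that("windowed datasets round-trip through CSV", {
  rec <- constant_recording(n = 150, fe = -20, ru = 5)
  w <- make_windows(rec)
  prefix <- file.path(withr::local_tempdir(), "wins")
  write_windows(w, prefix)
  back <- read_windows(prefix)
  expect_equal(back$mean_fe, w$mean_fe)
  expect_equal(back$fe_bin, w$fe_bin)
  expect_equal(back$meta$start_index, w$meta$start_index)
  expect_equal(back$x, w$x, tolerance = 1e-6)
})

test_that("FE binning follows the printed upper-inclusive inequalities", {
  expect_equal(bin_fe(50), 0L)
  expect_equal(bin_fe(45), 1L)
  expect_equal(bin_fe(15), 2L)
  expect_equal(bin_fe(0), 2L)
  expect_equal(bin_fe(-15), 3L)
  expect_equal(bin_fe(-45), 4L)
  expect_equal(bin_fe(-90), 4L)
  expect_error(bin_fe(NaN), "non-finite")
})

test_that("RU binning resolves the +10 boundary to the radial bin", {
  expect_equal(bin_ru(10), 0L)
  expect_equal(bin_ru(25), 0L)
  expect_equal(bin_ru(0), 1L)
  expect_equal(bin_ru(9.999), 1L)
  expect_equal(bin_ru(-10), 2L)
  expect_equal(bin_ru(-30), 2L)
  expect_error(bin_ru(Inf), "non-finite")
})

test_that("binning is exhaustive and mutually exclusive over the angle range", {
  set.seed(99)
  theta <- c(runif(20000, -90, 90), 45, 15, -15, -45, 10, -10,
             45 + 1e-9, 15 - 1e-9, -45 - 1e-12)
  fe <- bin_fe(theta)
  ru <- bin_ru(theta)
  expect_true(all(fe %in% 0:4))
  expect_true(all(ru %in% 0:2))
  # exclusivity: recompute membership from the interval definitions
  in_fe <- cbind(theta > 45,
                 theta <= 45 & theta > 15,
                 theta <= 15 & theta > -15,
                 theta <= -15 & theta > -45,
                 theta <= -45)
  expect_equal(rowSums(in_fe), rep(1, length(theta)))
  expect_equal(fe, unname(apply(in_fe, 1, which) - 1L))
})
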