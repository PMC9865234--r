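# Preprocessing: zero-lag filtering, 0-1 normalization, sliding-window
# restructuring of the 12 inertial channels, and posture binning.
#
# Pipeline order is filter -> normalize -> window; window labels are the mean
# of the 10 central samples of the (filtered) angle channels, binned into
# 5 FE classes and 3 RU classes.

#' Zero-lag Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering; output length equals
#' input length and DC gain is exactly 1.
#'
#' @param x Numeric vector.
#' @param cutoff_hz Cut-off frequency in Hz, `0 < cutoff_hz < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Filter order before the bidirectional pass (default 4, the
#'   usual choice for movement kinematics).
#' @return Filtered numeric vector, same length as `x`.
#' @export
zero_lag_lowpass <- function(x, cutoff_hz, fs, order = 4) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2, order >= 1)
  min_len <- 3L * (2L * order + 1L)
  if (length(x) <= min_len) {
    stop("signal too short for zero-lag filtering: length ", length(x),
         ", need more than ", min_len, " samples")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  filtfilt_pad(bf$b, bf$a, x)
}

# Steady-state initial filter state for a step input of unit height
# (direct-form II transposed), so the filter starts transient-free.
lfilter_zi <- function(b, a) {
  b <- b / a[1]
  a <- a / a[1]
  n <- max(length(a), length(b))
  length(a) <- n; length(b) <- n
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  comp <- rbind(-a[-1], cbind(diag(n - 2L), 0))  # companion matrix of a
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(comp), B)
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initial conditions at both ends.
filtfilt_pad <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * max(length(a), length(b)))
  xp <- c(2 * x[1] - x[(pad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_cpp(b, a, xp, zi * xp[1])
  y <- rev(lfilter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

#' Filter one recording's angle and inertial channels
#'
#' Angles are low-passed at `cutoff_angles_hz` (used for window labels);
#' inertial channels at `cutoff_imu_hz` (used, after normalization, as model
#' input).
#'
#' @param recording A `wp_recording`.
#' @param cutoff_angles_hz,cutoff_imu_hz Cut-off frequencies, Hz.
#' @return The recording with filtered channels and `filtered = TRUE`.
#' @export
filter_recording <- function(recording, cutoff_angles_hz = 5, cutoff_imu_hz = 6) {
  fs <- recording$fs
  for (ch in c("theta_fe", "theta_ru", "theta_ps")) {
    recording$angles[[ch]] <- zero_lag_lowpass(recording$angles[[ch]],
                                               cutoff_angles_hz, fs)
  }
  recording$imu <- apply(recording$imu, 2, zero_lag_lowpass,
                         cutoff_hz = cutoff_imu_hz, fs = fs)
  recording$filtered <- TRUE
  recording
}

#' Fit per-channel min/max normalization on training recordings
#'
#' @param recordings List of (filtered) `wp_recording`s forming the training
#'   partition. Parameters must be fitted on training data only; applying
#'   them to held-out data clips to the training range.
#' @return A `wp_norm_params` with per-channel `min` and `max` (12 each).
#' @export
fit_normalization <- function(recordings) {
  stopifnot(length(recordings) >= 1)
  mats <- lapply(recordings, function(r) r$imu)
  mins <- do.call(pmin, lapply(mats, function(m) apply(m, 2, min)))
  maxs <- do.call(pmax, lapply(mats, function(m) apply(m, 2, max)))
  structure(list(min = mins, max = maxs), class = "wp_norm_params")
}

#' Apply min/max normalization to an inertial matrix
#'
#' Maps each channel value `v` to `(v - min) / (max - min)` and clips to
#' `[0, 1]` so unseen extremes in held-out data cannot leave the training
#' range. A degenerate channel (`max == min`) maps to 0 with a warning.
#'
#' @param imu n x 12 inertial matrix.
#' @param params A [fit_normalization()] result.
#' @return Normalized matrix of the same shape.
#' @export
apply_normalization <- function(imu, params) {
  stopifnot(inherits(params, "wp_norm_params"), ncol(imu) == length(params$min))
  rng <- params$max - params$min
  degen <- rng <= 0
  if (any(degen)) {
    warning("degenerate channel(s) mapped to 0: ",
            paste(colnames(imu)[degen], collapse = ", "))
    rng[degen] <- 1
  }
  out <- sweep(sweep(imu, 2, params$min, "-"), 2, rng, "/")
  out[, degen] <- 0
  pmin(pmax(out, 0), 1)  # argument order matters: keep the matrix attributes
}

#' Bin a flexion/extension angle into the 5-class posture scheme
#'
#' Bins (upper edge inclusive, lower edge exclusive):
#' 0: theta > 45; 1: 45 >= theta > 15; 2: 15 >= theta > -15;
#' 3: -15 >= theta > -45; 4: -45 >= theta. Degrees, flexion positive.
#'
#' @param theta Numeric vector of angles in degrees (finite).
#' @return Integer vector of bin indices 0..4.
#' @export
bin_fe <- function(theta) {
  if (any(!is.finite(theta))) stop("non-finite angle passed to bin_fe")
  ifelse(theta > 45, 0L,
  ifelse(theta > 15, 1L,
  ifelse(theta > -15, 2L,
  ifelse(theta > -45, 3L, 4L))))
}

#' Bin a radial/ulnar-deviation angle into the 3-class posture scheme
#'
#' Bins: 0: theta >= 10 (radial); 1: 10 > theta > -10 (neutral);
#' 2: theta <= -10 (ulnar). The boundary value +10 belongs to the radial
#' bin. Degrees, radial deviation positive.
#'
#' @param theta Numeric vector of angles in degrees (finite).
#' @return Integer vector of bin indices 0..2.
#' @export
bin_ru <- function(theta) {
  if (any(!is.finite(theta))) stop("non-finite angle passed to bin_ru")
  ifelse(theta >= 10, 0L, ifelse(theta > -10, 1L, 2L))
}

#' Describe the active bin schemes
#'
#' @return A list of the two `BinScheme`s with edges (degrees) and boundary
#'   rules.
#' @export
bin_schemes <- function() {
  list(
    FE5 = list(name = "FE5", edges = c(45, 15, -15, -45), n_classes = 5L,
               boundary_rule = "upper edge inclusive, lower edge exclusive"),
    RU3 = list(name = "RU3", edges = c(10, -10), n_classes = 3L,
               boundary_rule = "+10 belongs to the radial (top) bin; -10 to the ulnar bin")
  )
}

#' Restructure a recording into overlapping 12 x 100 windows
#'
#' Windows of `window_len` samples start every `window_len - overlap` samples
#' (defaults: 100-sample windows, 90-sample overlap, i.e. 10 windows per
#' second at 100 Hz). Each window's posture label is the mean of the 10
#' central samples (0-based samples 45..54) of the angle channels, binned
#' with [bin_fe()]/[bin_ru()].
#'
#' @param recording A (filtered, normalized) `wp_recording`.
#' @param window_len,overlap Window length and overlap in samples.
#' @param include_rom_sweeps Keep windows that overlap the scripted
#'   range-of-motion sweeps at the start/end of the recording (default TRUE).
#' @param include_x Materialize the 12 x 100 input blocks (set FALSE for
#'   label-only analyses to save memory).
#' @return A `wp_windows` object: a list with `x` (n x 1200 matrix of windows
#'   flattened channel-fastest, or NULL), `mean_fe`, `mean_ru`, `fe_bin`,
#'   `ru_bin` and a `meta` data frame (participant, session, repetition,
#'   task, start_index).
#' @export
make_windows <- function(recording, window_len = 100L, overlap = 90L,
                         include_rom_sweeps = TRUE, include_x = TRUE) {
  stopifnot(overlap >= 0, overlap < window_len)
  stride <- window_len - overlap
  n <- nrow(recording$angles)
  if (n < window_len) {
    warning("recording shorter than one window (", n, " < ", window_len,
            "); returning no windows")
    return(empty_windows(include_x, window_len))
  }
  starts <- seq(0L, n - window_len, by = stride)  # 0-based offsets
  if (!include_rom_sweeps) {
    sw <- recording$sweep_samples %||% 0L
    starts <- starts[starts >= sw & (starts + window_len) <= (n - sw)]
    if (length(starts) == 0L) {
      warning("no windows outside the range-of-motion sweeps")
      return(empty_windows(include_x, window_len))
    }
  }
  nw <- length(starts)
  # central 10 samples, 0-based 45..54 for a 100-sample window
  center_rel <- (window_len %/% 2L - 5L):(window_len %/% 2L + 4L)
  idx_center <- outer(starts, center_rel + 1L, "+")
  mean_fe <- rowMeans(matrix(recording$angles$theta_fe[idx_center], nw))
  mean_ru <- rowMeans(matrix(recording$angles$theta_ru[idx_center], nw))

  x <- NULL
  if (include_x) {
    nch <- ncol(recording$imu)
    x <- matrix(0, nw, nch * window_len)
    for (j in seq_len(window_len)) {
      x[, (nch * (j - 1L) + 1L):(nch * j)] <- recording$imu[starts + j, ]
    }
  }
  meta <- data.frame(
    participant = recording$meta$participant,
    session = recording$meta$session,
    repetition = recording$meta$repetition,
    task = recording$meta$task,
    start_index = starts,
    stringsAsFactors = FALSE
  )
  new_windows(x, mean_fe, mean_ru, meta)
}

new_windows <- function(x, mean_fe, mean_ru, meta) {
  structure(list(
    x = x,
    mean_fe = mean_fe,
    mean_ru = mean_ru,
    fe_bin = bin_fe(mean_fe),
    ru_bin = bin_ru(mean_ru),
    meta = meta
  ), class = "wp_windows")
}

empty_windows <- function(include_x, window_len) {
  structure(list(
    x = if (include_x) matrix(0, 0, 12L * window_len) else NULL,
    mean_fe = numeric(0), mean_ru = numeric(0),
    fe_bin = integer(0), ru_bin = integer(0),
    meta = data.frame(participant = integer(0), session = integer(0),
                      repetition = integer(0), task = character(0),
                      start_index = integer(0))
  ), class = "wp_windows")
}

#' Number of windows in a `wp_windows` object
#' @param w A `wp_windows`.
#' @return Integer count.
#' @export
n_windows <- function(w) length(w$mean_fe)

#' Subset a `wp_windows` object by index
#' @param w A `wp_windows`.
#' @param idx Integer indices (may repeat: resampling draws with replacement).
#' @return A `wp_windows` with the selected windows, in `idx` order.
#' @export
windows_subset <- function(w, idx) {
  structure(list(
    x = if (is.null(w$x)) NULL else w$x[idx, , drop = FALSE],
    mean_fe = w$mean_fe[idx],
    mean_ru = w$mean_ru[idx],
    fe_bin = w$fe_bin[idx],
    ru_bin = w$ru_bin[idx],
    meta = w$meta[idx, , drop = FALSE]
  ), class = "wp_windows")
}

#' Concatenate `wp_windows` objects
#' @param ... `wp_windows` objects (or a single list of them).
#' @return One combined `wp_windows`.
#' @export
windows_concat <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "wp_windows")) {
    parts <- parts[[1]]
  }
  parts <- Filter(function(p) n_windows(p) > 0, parts)
  if (length(parts) == 0L) return(empty_windows(TRUE, 100L))
  has_x <- !vapply(parts, function(p) is.null(p$x), TRUE)
  x <- if (all(has_x)) do.call(rbind, lapply(parts, function(p) p$x)) else NULL
  structure(list(
    x = x,
    mean_fe = unlist(lapply(parts, function(p) p$mean_fe)),
    mean_ru = unlist(lapply(parts, function(p) p$mean_ru)),
    fe_bin = unlist(lapply(parts, function(p) p$fe_bin)),
    ru_bin = unlist(lapply(parts, function(p) p$ru_bin)),
    meta = do.call(rbind, lapply(parts, function(p) p$meta))
  ), class = "wp_windows")
}

#' @export
print.wp_windows <- function(x, ...) {
  cat("<wp_windows> ", n_windows(x), " windows",
      if (is.null(x$x)) " (labels only)" else "", "\n", sep = "")
  if (n_windows(x) > 0) {
    cat("  FE bins:", paste(sprintf("%d:%d", 0:4, tabulate(x$fe_bin + 1L, 5L)),
                            collapse = " "), "\n")
  }
  invisible(x)
}

#' Write / read a windowed dataset
#'
#' Persists a `wp_windows` object as plain text: `<prefix>_labels.csv` with
#' the labels and window metadata, and (when input blocks are present)
#' `<prefix>_X.csv` with one flattened 12 x 100 block per row. Suited to
#' small fixtures and exports; large window sets are regenerated in code.
#'
#' @param windows A `wp_windows`.
#' @param prefix File path prefix.
#' @return `write_windows` returns `prefix` invisibly; `read_windows` the
#'   `wp_windows`.
#' @export
write_windows <- function(windows, prefix) {
  lab <- cbind(windows$meta,
               data.frame(mean_fe = windows$mean_fe, mean_ru = windows$mean_ru,
                          fe_bin = windows$fe_bin, ru_bin = windows$ru_bin))
  utils::write.csv(lab, paste0(prefix, "_labels.csv"), row.names = FALSE)
  if (!is.null(windows$x)) {
    utils::write.csv(windows$x, paste0(prefix, "_X.csv"), row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_windows
#' @export
read_windows <- function(prefix) {
  lab <- utils::read.csv(paste0(prefix, "_labels.csv"))
  xp <- paste0(prefix, "_X.csv")
  x <- if (file.exists(xp)) as.matrix(utils::read.csv(xp)) else NULL
  if (!is.null(x)) dimnames(x) <- NULL
  new_windows(x, lab$mean_fe, lab$mean_ru,
              lab[c("participant", "session", "repetition", "task",
                    "start_index")])
}

#' Preprocess a whole cohort into labelled windows
#'
#' Applies the standard pipeline per recording — filter (angles 5 Hz,
#' inertial 6 Hz), normalize with `params`, window — and returns one
#' `wp_windows` per recording.
#'
#' @param cohort A `wp_cohort`.
#' @param params `wp_norm_params` fitted on the training partition, or NULL
#'   to skip normalization (label-only workflows).
#' @param cutoff_angles_hz,cutoff_imu_hz Filter cut-offs, Hz.
#' @param window_len,overlap,include_rom_sweeps,include_x Passed to
#'   [make_windows()].
#' @return List of `wp_windows`, one per recording.
#' @export
preprocess_cohort <- function(cohort, params = NULL,
                              cutoff_angles_hz = 5, cutoff_imu_hz = 6,
                              window_len = 100L, overlap = 90L,
                              include_rom_sweeps = TRUE, include_x = TRUE) {
  lapply(cohort, function(rec) {
    rec <- filter_recording(rec, cutoff_angles_hz, cutoff_imu_hz)
    if (!is.null(params)) rec$imu <- apply_normalization(rec$imu, params)
    make_windows(rec, window_len, overlap, include_rom_sweeps, include_x)
  })
}
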