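# Class balancing by range-of-motion histogram: per recording, the target
# angle is rounded to the nearest degree, one representative window is drawn
# from every occupied 1-degree bin, and representatives are then sampled with
# replacement until exactly n_per_recording examples exist. This flattens the
# strongly neutral-dominated posture distribution before training.

#' Resampling plan
#'
#' @param target_channel `"fe"` or `"ru"`: the angular channel whose
#'   distribution is flattened. Balance the channel the model will predict;
#'   flattening FE cannot simultaneously flatten RU.
#' @param n_per_recording Examples drawn per recording (default 250, giving
#'   3000 per participant across their 12 recordings).
#' @param seed Integer seed for the draws.
#' @return A `wp_resample_plan`.
#' @export
resample_plan <- function(target_channel = c("fe", "ru"),
                          n_per_recording = 250L, seed = 1L) {
  target_channel <- match.arg(target_channel)
  stopifnot(n_per_recording >= 1)
  structure(list(target_channel = target_channel,
                 n_per_recording = as.integer(n_per_recording),
                 seed = as.integer(seed)),
            class = "wp_resample_plan")
}

# Round half away from zero, the pinned rounding rule for 1-degree binning
# (base round() rounds half to even, which would split boundary degrees
# inconsistently between adjacent bins across the sign change).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Balance one recording's windows across its range of motion
#'
#' Step 1: round each window's target mean angle to the nearest degree.
#' Step 2: draw one window uniformly at random from each occupied 1-degree
#' bin. Step 3: draw uniformly with replacement from those representatives
#' until exactly `plan$n_per_recording` examples exist. Output order is draw
#' order (representatives first, in angle order). Every output window is a
#' member of the input set; if more bins are occupied than examples
#' requested, the representative set is uniformly subsampled first.
#'
#' @param windows `wp_windows` from a single recording.
#' @param plan A [resample_plan()].
#' @param seed Seed for this recording's draws (defaults to a seed derived
#'   from the plan seed and the recording's metadata, so results do not
#'   depend on processing order).
#' @return A `wp_windows` of exactly `plan$n_per_recording` windows.
#' @export
balance_recording <- function(windows, plan, seed = NULL) {
  if (n_windows(windows) == 0L) stop("cannot balance an empty window set")
  key <- unique(windows$meta[c("participant", "session", "repetition", "task")])
  if (nrow(key) != 1L) {
    stop("balance_recording expects windows from a single recording; got ",
         nrow(key), " distinct recordings")
  }
  if (is.null(seed)) {
    seed <- derive_seed(plan$seed, "balance", plan$target_channel,
                        key$participant, key$session, key$repetition, key$task)
  }
  ang <- switch(plan$target_channel, fe = windows$mean_fe, ru = windows$mean_ru)
  deg <- round_half_away(ang)
  n <- plan$n_per_recording
  with_seed(seed, {
    bins <- sort(unique(deg))
    reps <- vapply(bins, function(b) {
      cand <- which(deg == b)
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, integer(1))
    if (length(reps) > n) {
      reps <- sort(sample(reps, n))
    }
    extra <- if (n > length(reps)) {
      sample(reps, n - length(reps), replace = TRUE)
    } else integer(0)
    out <- windows_subset(windows, c(reps, extra))
    attr(out, "resample_log") <- list(
      plan = unclass(plan), seed = seed,
      counts_before = as.list(degree_histogram(windows, plan$target_channel)),
      counts_after = as.list(degree_histogram(out, plan$target_channel)))
    out
  })
}

#' Write the resampling sidecar log of a balanced window set
#'
#' Records the plan, seed and per-1-degree-bin counts before/after
#' balancing, as attached by [balance_recording()].
#'
#' @param windows A balanced `wp_windows`.
#' @param path JSON output path.
#' @return Invisibly, `path`.
#' @export
write_resample_log <- function(windows, path) {
  log <- attr(windows, "resample_log")
  if (is.null(log)) stop("windows carry no resampling log")
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Balance every recording present in `windows` (grouped by metadata) and
# concatenate; no completeness requirement. Used for multi-participant
# training partitions.
balance_by_recording <- function(windows, plan) {
  key <- interaction(windows$meta$participant, windows$meta$session,
                     windows$meta$repetition, windows$meta$task, drop = TRUE)
  parts <- lapply(split(seq_len(n_windows(windows)), key), function(idx) {
    balance_recording(windows_subset(windows, idx), plan)
  })
  windows_concat(parts)
}

#' Balance a full participant (12 recordings) to 12 x n_per_recording windows
#'
#' @param windows `wp_windows` holding all of one participant's recordings
#'   (2 sessions x 2 repetitions x 3 tasks).
#' @param plan A [resample_plan()].
#' @return A `wp_windows` of `12 * plan$n_per_recording` examples,
#'   approximately evenly distributed across the participant's range of
#'   motion.
#' @export
balance_participant <- function(windows, plan) {
  if (n_windows(windows) == 0L) stop("cannot balance an empty window set")
  p <- unique(windows$meta$participant)
  if (length(p) != 1L) {
    stop("balance_participant expects one participant; got ",
         paste(p, collapse = ", "))
  }
  want <- expand.grid(session = 1:2, repetition = 1:2, task = WP_TASKS,
                      stringsAsFactors = FALSE)
  have <- unique(windows$meta[c("session", "repetition", "task")])
  missing <- want[!do.call(paste, want) %in% do.call(paste, have), ]
  if (nrow(missing) > 0L) {
    stop("participant ", p, " is missing recordings: ",
         paste(sprintf("(S%d,R%d,%s)", missing$session, missing$repetition,
                       missing$task), collapse = " "))
  }
  balance_by_recording(windows, plan)
}

#' Summarize 1-degree-bin occupancy before/after balancing
#'
#' @param windows A `wp_windows`.
#' @param target_channel `"fe"` or `"ru"`.
#' @return Named integer vector of window counts per occupied 1-degree bin.
#' @export
degree_histogram <- function(windows, target_channel = c("fe", "ru")) {
  target_channel <- match.arg(target_channel)
  ang <- switch(target_channel, fe = windows$mean_fe, ru = windows$mean_ru)
  table(round_half_away(ang))
}
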