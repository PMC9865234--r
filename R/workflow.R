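# Run configuration and the command-line pipeline: simulate -> preprocess ->
# resample -> train -> evaluate -> report, driven by one global seed.

#' Build a full run configuration
#'
#' One global seed deterministically derives every stage seed (hash-chained
#' via [derive_seed()]), so a run is reproducible from its stored
#' configuration alone.
#'
#' @param seed Global integer seed.
#' @param n_participants Cohort size.
#' @param simulate A [sim_config()]; defaults to one seeded from `seed`.
#' @param preprocess List: `cutoff_angles_hz`, `cutoff_imu_hz`, `window_len`,
#'   `overlap`, `include_rom_sweeps`.
#' @param resample List: `n_per_recording`.
#' @param train A [train_config()]; defaults seeded from `seed`.
#' @param evaluate List: `targets` (subset of `c("fe","ru")`).
#' @return A `wp_run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_participants = 10L,
                       simulate = sim_config(seed = derive_seed(seed, "simulate")),
                       preprocess = list(cutoff_angles_hz = 5, cutoff_imu_hz = 6,
                                         window_len = 100L, overlap = 90L,
                                         include_rom_sweeps = TRUE),
                       resample = list(n_per_recording = 250L),
                       train = train_config(seed = derive_seed(seed, "train")),
                       evaluate = list(targets = c("fe", "ru"))) {
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 simulate = simulate, preprocess = preprocess,
                 resample = resample, train = train, evaluate = evaluate),
            class = "wp_run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a `wp_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  sim_args <- y$simulate %||% list()
  if (!is.null(sim_args$duration_s)) sim_args$duration_s <- unlist(sim_args$duration_s)
  if (!is.null(sim_args$task_mixture)) {
    sim_args$task_mixture <- lapply(sim_args$task_mixture, function(p) {
      if (!is.null(p$excursion_peak)) p$excursion_peak <- unlist(p$excursion_peak)
      p
    })
  }
  sim_args$seed <- sim_args$seed %||% derive_seed(seed, "simulate")
  train_args <- y$train %||% list()
  train_args$seed <- train_args$seed %||% derive_seed(seed, "train")
  args <- list(seed = seed,
               simulate = do.call(sim_config, sim_args),
               train = do.call(train_config, train_args))
  if (!is.null(y$n_participants)) args$n_participants <- y$n_participants
  for (k in c("preprocess", "resample", "evaluate")) {
    if (!is.null(y[[k]])) {
      defaults <- formals(run_config)[[k]]
      merged <- eval(defaults, list(seed = seed))
      merged[names(y[[k]])] <- y[[k]]
      if (k == "evaluate") merged$targets <- unlist(merged$targets)
      args[[k]] <- merged
    }
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config A `wp_run_config`.
#' @export
write_run_config <- function(config, path) {
  # named atomic vectors (e.g. per-task durations) must become YAML maps,
  # not bare sequences, so names survive the round trip
  to_yamlable <- function(x) {
    if (is.list(x)) lapply(x, to_yamlable)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(to_yamlable(unclass(config)), path)
  invisible(path)
}

prepare_output_dir <- function(output_dir, force) {
  if (dir.exists(output_dir) && length(list.files(output_dir)) > 0 && !force) {
    stop("output directory '", output_dir,
         "' exists and is not empty; use force = TRUE (--force)")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
}

stage_log <- function(output_dir, stage, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...))
  message(line)
  cat(line, "\n", file = file.path(output_dir, "run.log"), append = TRUE)
}

#' Simulate a cohort and write it to disk
#'
#' @param config A [run_config()].
#' @param output_dir Output directory for the recording CSVs and manifest.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, the manifest path.
#' @export
cmd_simulate <- function(config = run_config(), output_dir, force = FALSE) {
  prepare_output_dir(output_dir, force)
  stage_log(output_dir, "simulate",
            "generating %d participants x 12 recordings (seed %d)",
            config$n_participants, config$simulate$seed)
  cohort <- generate_cohort(config$n_participants, config$simulate)
  mp <- write_cohort(cohort, output_dir, force = TRUE)
  stage_log(output_dir, "simulate", "%d recordings written (durations: %s s)",
            length(cohort),
            paste(names(config$simulate$duration_s),
                  config$simulate$duration_s, sep = "=", collapse = ", "))
  invisible(mp)
}

#' Run the full pipeline and write the evaluation report
#'
#' Executes simulate -> preprocess -> resample -> train -> evaluate and
#' writes every stage's artifacts (cohort CSVs, run config, evaluation
#' report, logs) under `output_dir`. Every artifact embeds the configuration
#' hash so outputs of different configurations cannot be mixed.
#'
#' @param config A [run_config()].
#' @param output_dir Output directory.
#' @param force Overwrite a non-empty output directory.
#' @param write_recordings Also write the per-recording CSVs (default TRUE).
#' @return The `wp_eval_report`, invisibly.
#' @export
cmd_run_all <- function(config = run_config(), output_dir, force = FALSE,
                        write_recordings = TRUE) {
  prepare_output_dir(output_dir, force)
  hash <- config_hash(rapply(unclass(config), identity, how = "list"))
  write_run_config(config, file.path(output_dir, "config.yaml"))

  stage_log(output_dir, "simulate", "cohort of %d participants (hash %s)",
            config$n_participants, hash)
  cohort <- generate_cohort(config$n_participants, config$simulate)
  stage_log(output_dir, "simulate", "%d recordings generated", length(cohort))
  if (write_recordings) {
    write_cohort(cohort, file.path(output_dir, "cohort"), force = TRUE)
  }

  stage_log(output_dir, "evaluate",
            "LOSO + refinement over %d folds, targets: %s",
            config$n_participants,
            paste(config$evaluate$targets, collapse = ", "))
  report <- loso_evaluate(
    cohort,
    targets = config$evaluate$targets,
    plan_seed = derive_seed(config$seed, "resample"),
    n_per_recording = config$resample$n_per_recording,
    config = config$train,
    include_rom_sweeps = config$preprocess$include_rom_sweeps,
    verbose = TRUE)

  for (target in names(report$targets)) {
    s <- report$targets[[target]]
    stage_log(output_dir, "report",
              "%s: accuracy %.3f +/- %.3f, kappa %.3f +/- %.3f (%s)",
              toupper(target), s$mean_accuracy, s$se_accuracy,
              s$mean_kappa, s$se_kappa, s$kappa_label)
  }
  write_report(report, output_dir, extra = list(config_hash = hash))
  invisible(report)
}
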