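# Window classifier: model construction, two-phase training (initial +
# subject-specific refinement), and prediction.

#' Architecture shape chain
#'
#' Feature-map dimensions of the fixed architecture under valid (no-padding)
#' convolutions: 12x100x1 -> 10x98x32 -> 5x49x32 -> 3x47x64 -> 1x23x64 ->
#' flatten 1472 -> dense 4096 -> n_classes.
#'
#' @param n_classes Number of output classes.
#' @return List of named stage dimensions, including `flatten_len`.
#' @export
cnn_shape_chain <- function(n_classes = 5L) {
  conv <- function(d) c(d[1] - 2L, d[2] - 2L)
  pool <- function(d) c(d[1] %/% 2L, d[2] %/% 2L)
  d0 <- c(12L, 100L)
  d1 <- conv(d0); d2 <- pool(d1); d3 <- conv(d2); d4 <- pool(d3)
  list(input = c(d0, 1L),
       conv1 = c(d1, 32L), pool1 = c(d2, 32L),
       conv2 = c(d3, 64L), pool2 = c(d4, 64L),
       flatten_len = as.integer(64L * prod(d4)),
       dense = 4096L,
       output = as.integer(n_classes))
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build an untrained window classifier
#'
#' Initializes the fixed convolutional architecture (two 3x3 conv + 2x2
#' max-pool stages, a 4096-unit dense layer with 80% dropout, softmax
#' output) with Glorot-uniform weights. The target channel is implied by the
#' class count: 5 classes = flexion/extension, 3 = radial/ulnar deviation.
#'
#' @param n_classes Output classes (>= 2).
#' @param seed Integer seed; one seed gives bit-identical initial weights.
#' @return A `wp_model`.
#' @export
build_model <- function(n_classes, seed = 1L) {
  stopifnot(n_classes >= 2)
  shapes <- cnn_shape_chain(n_classes)
  flat <- shapes$flatten_len
  weights <- with_seed(seed, list(
    W1 = glorot(32, 9, 9, 9 * 32),
    b1 = rep(0, 32),
    W2 = glorot(64, 9 * 32, 9 * 32, 9 * 64),
    b2 = rep(0, 64),
    W3 = glorot(4096, flat, flat, 4096),
    b3 = rep(0, 4096),
    W4 = glorot(n_classes, 4096, 4096, n_classes),
    b4 = rep(0, n_classes)
  ))
  structure(list(
    n_classes = as.integer(n_classes),
    target = if (n_classes == 5L) "fe" else if (n_classes == 3L) "ru" else NA_character_,
    shapes = shapes,
    weights = weights,
    norm = NULL,
    train_participants = NULL,
    log = list(),
    seed = as.integer(seed)
  ), class = "wp_model")
}

#' @export
print.wp_model <- function(x, ...) {
  trained <- length(x$log) > 0
  cat("<wp_model> ", x$n_classes, "-class (", x$target, ") window classifier; ",
      if (trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Training configuration for the two-phase protocol
#'
#' Initial training uses a 10% validation split with early stopping after 10
#' epochs without validation-loss improvement (hard limit 500 epochs).
#' Refinement runs at a 10-times-lower learning rate with patience 1 and a
#' hard limit of 50 epochs. Reported weights are those of the best
#' validation epoch.
#'
#' @param val_fraction Validation fraction of the (shuffled) training set.
#' @param initial,refine Lists with `patience`, `max_epochs`,
#'   `learning_rate`. The refinement learning rate must be one tenth of the
#'   initial one.
#' @param batch_size Mini-batch size.
#' @param dropout Dropout rate of the dense layer.
#' @param seed Integer seed for shuffling, dropout and weight updates.
#' @return A `wp_train_config`.
#' @export
train_config <- function(val_fraction = 0.10,
                         initial = list(patience = 10L, max_epochs = 500L,
                                        learning_rate = 1e-3),
                         refine = list(patience = 1L, max_epochs = 50L,
                                       learning_rate = initial$learning_rate / 10),
                         batch_size = 64L,
                         dropout = 0.80,
                         seed = 1L) {
  stopifnot(val_fraction >= 0, val_fraction < 1,
            initial$patience >= 1, refine$patience >= 1,
            dropout >= 0, dropout < 1)
  if (abs(refine$learning_rate - initial$learning_rate / 10) >
      1e-12 * max(1, initial$learning_rate)) {
    stop("refinement learning rate must be initial learning rate / 10")
  }
  structure(list(val_fraction = val_fraction, initial = initial,
                 refine = refine, batch_size = as.integer(batch_size),
                 dropout = dropout, seed = as.integer(seed)),
            class = "wp_train_config")
}

window_labels <- function(model, windows) {
  switch(model$target,
         fe = windows$fe_bin,
         ru = windows$ru_bin,
         stop("model has no implied target channel; need 5 or 3 classes"))
}

run_training_phase <- function(model, windows, phase, cfg, phase_seed) {
  y <- window_labels(model, windows)
  if (length(unique(y)) < 2L) {
    stop("training labels contain fewer than 2 classes")
  }
  n <- n_windows(windows)
  ord <- with_seed(phase_seed, sample.int(n))
  n_val <- floor(cfg$val_fraction * n)
  val_idx <- if (n_val > 0) ord[(n - n_val + 1L):n] else integer(0)
  train_idx <- if (n_val > 0) ord[1:(n - n_val)] else ord
  fit <- cnn_train_cpp(windows$x, as.integer(y), model$weights,
                       model$n_classes,
                       lr = phase$learning_rate,
                       batch_size = cfg$batch_size,
                       max_epochs = as.integer(phase$max_epochs),
                       patience = as.integer(phase$patience),
                       train_idx = as.integer(train_idx),
                       val_idx = as.integer(val_idx),
                       keep_prob = 1 - cfg$dropout,
                       seed = phase_seed)
  fit$weights[c("b1", "b2", "b3", "b4")] <-
    lapply(fit$weights[c("b1", "b2", "b3", "b4")], as.numeric)
  model$weights <- fit$weights
  list(model = model,
       log = list(stop_epoch = fit$stop_epoch, best_epoch = fit$best_epoch,
                  stop_reason = fit$stop_reason,
                  best_monitor = fit$best_monitor,
                  train_loss = fit$train_loss, val_loss = fit$val_loss))
}

#' Initial training on the balanced multi-participant training set
#'
#' @param model An untrained (or previously trained) `wp_model`.
#' @param windows Balanced training windows; must exclude the held-out test
#'   participant entirely.
#' @param config A [train_config()].
#' @param norm Optional `wp_norm_params` to store with the model (the
#'   parameters the training windows were normalized with).
#' @return The fitted `wp_model` with a training log.
#' @export
train_initial <- function(model, windows, config = train_config(), norm = NULL) {
  res <- run_training_phase(model, windows, config$initial, config,
                            derive_seed(config$seed, "initial", model$target))
  model <- res$model
  model$norm <- norm %||% model$norm
  model$train_participants <- sort(unique(windows$meta$participant))
  model$log$initial <- res$log
  model
}

#' Subject-specific refinement on the test participant's first session
#'
#' Fine-tunes the fitted model on balanced windows drawn exclusively from
#' session 1 of the held-out participant, at one tenth of the initial
#' learning rate with patience 1. Windows from any other participant, from
#' session 2, or from a participant seen in initial training raise an error
#' (leakage guard).
#'
#' @param model A `wp_model` after [train_initial()].
#' @param windows Balanced session-1 windows of the test participant.
#' @param config A [train_config()].
#' @param test_participant Optional expected participant id to check against.
#' @return The refined `wp_model`.
#' @export
refine <- function(model, windows, config = train_config(),
                   test_participant = NULL) {
  p <- unique(windows$meta$participant)
  if (length(p) != 1L) {
    stop("refinement windows must come from a single participant; got ",
         paste(p, collapse = ", "))
  }
  if (!is.null(test_participant) && p != test_participant) {
    stop("refinement windows belong to participant ", p,
         ", expected test participant ", test_participant)
  }
  if (p %in% (model$train_participants %||% integer(0))) {
    stop("leakage: refinement participant ", p,
         " was present in the initial training set")
  }
  s <- unique(windows$meta$session)
  if (!all(s == 1)) {
    stop("refinement windows must come from session 1 only; got session(s) ",
         paste(sort(s), collapse = ", "))
  }
  res <- run_training_phase(model, windows, config$refine, config,
                            derive_seed(config$seed, "refine", model$target, p))
  model <- res$model
  model$log$refine <- res$log
  model
}

#' Class probabilities for a set of windows
#'
#' @param model A fitted `wp_model`.
#' @param windows `wp_windows` normalized with the model's stored
#'   normalization parameters.
#' @return n x n_classes matrix of softmax probabilities.
#' @export
predict_proba <- function(model, windows) {
  if (is.null(windows$x)) stop("windows carry no input blocks (include_x = FALSE)")
  if (ncol(windows$x) != 1200L) {
    stop("window shape mismatch: expected 12 x 100 blocks")
  }
  cnn_predict_cpp(windows$x, model$weights, model$n_classes)
}

#' Predicted posture bins for a set of windows
#'
#' Argmax over class probabilities; exact ties break toward the lower class
#' index.
#'
#' @inheritParams predict_proba
#' @return Integer vector of 0-based class indices, one per window.
#' @export
predict_bins <- function(model, windows) {
  p <- predict_proba(model, windows)
  as.integer(apply(p, 1, which.max) - 1L)
}

#' Save / load a fitted model bundle
#'
#' The bundle directory holds the weights (`weights.rds`), the
#' normalization parameters, the architecture description, and the training
#' log as JSON.
#'
#' @param model A `wp_model`.
#' @param dir Bundle directory (created if missing).
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$weights, file.path(dir, "weights.rds"))
  if (!is.null(model$norm)) saveRDS(model$norm, file.path(dir, "norm.rds"))
  meta <- list(n_classes = model$n_classes, target = model$target,
               shapes = model$shapes, seed = model$seed,
               train_participants = model$train_participants)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(model$log, file.path(dir, "training_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  model <- build_model(meta$n_classes, seed = meta$seed %||% 1L)
  model$weights <- readRDS(file.path(dir, "weights.rds"))
  np <- file.path(dir, "norm.rds")
  if (file.exists(np)) model$norm <- readRDS(np)
  model$train_participants <- meta$train_participants
  lf <- file.path(dir, "training_log.json")
  if (file.exists(lf)) model$log <- jsonlite::read_json(lf, simplifyVector = TRUE)
  model
}
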