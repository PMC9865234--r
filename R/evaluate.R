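# Agreement statistics and leave-one-subject-out evaluation with a
# subject-specific refinement step.

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with `p_o`
#' the observed agreement fraction and `p_e` the chance agreement implied by
#' the marginal label distributions. Returns 1 for perfect agreement with
#' degenerate marginals (`p_e == 1`).
#'
#' @param truth,pred Equal-length non-empty integer label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("label sequences differ in length (", length(truth), " vs ",
         length(pred), ")")
  }
  if (length(truth) == 0L) stop("empty label sequences")
  n <- length(truth)
  p_o <- mean(truth == pred)
  classes <- union(truth, pred)
  pt <- vapply(classes, function(k) mean(truth == k), 0)
  pp <- vapply(classes, function(k) mean(pred == k), 0)
  p_e <- sum(pt * pp)
  if (1 - p_e < .Machine$double.eps) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Landis-Koch qualitative label for a kappa value
#'
#' Poor (< 0), Slight [0, 0.20], Fair (0.20, 0.40], Moderate (0.40, 0.60],
#' Substantial (0.60, 0.80], Almost Perfect (0.80, 1].
#'
#' @param kappa Kappa in `[-1, 1]`.
#' @return Character label.
#' @export
landis_koch_label <- function(kappa) {
  if (!is.finite(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must lie in [-1, 1]")
  }
  if (kappa < 0) "Poor"
  else if (kappa <= 0.20) "Slight"
  else if (kappa <= 0.40) "Fair"
  else if (kappa <= 0.60) "Moderate"
  else if (kappa <= 0.80) "Substantial"
  else "Almost Perfect"
}

#' Contingency table of true vs predicted classes
#'
#' @param truth,pred Integer labels in `0..n_classes-1`; true class on rows,
#'   predicted on columns.
#' @param n_classes Number of classes.
#' @param normalize `"none"` for counts or `"row"` to divide each non-empty
#'   row by its sum (empty rows become NaN and are flagged by downstream
#'   summaries rather than divided).
#' @return `n_classes` x `n_classes` matrix.
#' @export
contingency_table <- function(truth, pred, n_classes,
                              normalize = c("none", "row")) {
  normalize <- match.arg(normalize)
  if (length(truth) != length(pred)) stop("label sequences differ in length")
  if (any(truth < 0 | truth >= n_classes | pred < 0 | pred >= n_classes)) {
    stop("labels out of range 0..", n_classes - 1)
  }
  tab <- matrix(0, n_classes, n_classes)
  for (i in seq_along(truth)) {
    tab[truth[i] + 1L, pred[i] + 1L] <- tab[truth[i] + 1L, pred[i] + 1L] + 1
  }
  if (normalize == "row") tab <- row_normalize(tab)
  tab
}

row_normalize <- function(tab) {
  rs <- rowSums(tab)
  out <- tab / rs
  out[rs == 0, ] <- NaN
  out
}

#' Within-k-bin rates per true class
#'
#' For each true class i of a row-normalized contingency matrix, the summed
#' probability of predictions within k bins of i (|i - j| <= k).
#'
#' @param p Square row-normalized contingency matrix.
#' @param k Bin tolerance (default 1).
#' @return Numeric vector of per-class rates (NaN for empty rows).
#' @export
within_k_bins <- function(p, k = 1L) {
  if (!is.matrix(p) || nrow(p) != ncol(p)) {
    stop("expected a square row-normalized contingency matrix")
  }
  K <- nrow(p)
  vapply(seq_len(K), function(i) {
    j <- which(abs(seq_len(K) - i) <= k)
    sum(p[i, j])
  }, 0)
}

# Identity keys used by the fold-isolation audit: a window is identified by
# its source recording and start offset.
window_keys <- function(w) {
  with(w$meta, paste(participant, session, repetition, task, start_index,
                     sep = ":"))
}

#' Audit fold isolation between test and training/refinement window sets
#'
#' Verifies by window identity (source recording plus start offset) that no
#' test window appears in the training or refinement set; called inside
#' [loso_evaluate()] for every fold.
#'
#' @param w_train,w_refine,w_test `wp_windows` sets of one fold.
#' @return TRUE invisibly; throws an error on any overlap.
#' @export
audit_fold_isolation <- function(w_train, w_refine, w_test) {
  test_keys <- window_keys(w_test)
  if (any(test_keys %in% window_keys(w_train)) ||
      any(test_keys %in% window_keys(w_refine))) {
    stop("fold isolation violated: test windows found in training or ",
         "refinement data")
  }
  invisible(TRUE)
}

fold_metrics <- function(truth, pred, n_classes, participant, target) {
  tab <- contingency_table(truth, pred, n_classes)
  list(test_participant = participant,
       target = target,
       n_test_windows = length(truth),
       accuracy = sum(diag(tab)) / length(truth),
       kappa = cohen_kappa(truth, pred),
       contingency = tab,
       truth = truth,
       pred = pred)
}

summarize_target <- function(folds, n_classes) {
  acc <- vapply(folds, `[[`, 0, "accuracy")
  kap <- vapply(folds, `[[`, 0, "kappa")
  nf <- length(folds)
  cum <- Reduce(`+`, lapply(folds, `[[`, "contingency"))
  cum_norm <- row_normalize(cum)
  if (any(rowSums(cum) == 0)) {
    warning("empty true-class row(s) in cumulative contingency table; ",
            "reported as NaN and excluded from within-1-bin averaging")
  }
  list(
    folds = folds,
    n_folds = nf,
    mean_accuracy = mean(acc),
    se_accuracy = stats::sd(acc) / sqrt(nf),
    mean_kappa = mean(kap),
    se_kappa = stats::sd(kap) / sqrt(nf),
    kappa_label = landis_koch_label(mean(kap)),
    contingency_counts = cum,
    contingency_row_norm = cum_norm,
    within_1_bin = within_k_bins(cum_norm, 1L)
  )
}

#' Leave-one-subject-out evaluation with refinement
#'
#' For every participant p: fit normalization on all other participants'
#' recordings, train the classifier on their balanced windows, refine on
#' balanced windows from session 1 of p, and test on all raw (un-resampled)
#' windows of p's session-2 recordings. A hash audit over window identities
#' guarantees no test window enters any training or refinement set.
#'
#' @param cohort A `wp_cohort`.
#' @param targets Subset of `c("fe", "ru")` to evaluate (two independent
#'   models are trained per fold, one per target).
#' @param plan_seed Seed for the resampling draws.
#' @param n_per_recording Balanced examples per recording (default 250).
#' @param config A [train_config()].
#' @param include_rom_sweeps Keep range-of-motion sweep windows (training and
#'   test).
#' @param verbose Print per-fold progress.
#' @return A `wp_eval_report`: per-target fold results, fold means with
#'   standard errors, Landis-Koch label, cumulative row-normalized
#'   contingency tables and within-1-bin rates.
#' @export
loso_evaluate <- function(cohort, targets = c("fe", "ru"), plan_seed = 1L,
                          n_per_recording = 250L, config = train_config(),
                          include_rom_sweeps = TRUE, verbose = FALSE) {
  targets <- match.arg(targets, c("fe", "ru"), several.ok = TRUE)
  participants <- sort(unique(vapply(cohort, function(r) r$meta$participant, 0)))
  if (length(participants) < 3L) {
    stop("leave-one-subject-out evaluation needs at least 3 participants")
  }
  filtered <- lapply(cohort, filter_recording)
  rec_participant <- vapply(filtered, function(r) r$meta$participant, 0)
  rec_session <- vapply(filtered, function(r) r$meta$session, 0)

  window_set <- function(recs, params) {
    windows_concat(lapply(recs, function(rec) {
      rec$imu <- apply_normalization(rec$imu, params)
      make_windows(rec, include_rom_sweeps = include_rom_sweeps)
    }))
  }

  folds <- list(fe = list(), ru = list())
  for (p in participants) {
    train_recs <- filtered[rec_participant != p]
    params <- fit_normalization(train_recs)
    w_train <- window_set(train_recs, params)
    w_refine_raw <- window_set(filtered[rec_participant == p & rec_session == 1],
                               params)
    w_test <- window_set(filtered[rec_participant == p & rec_session == 2],
                         params)

    audit_fold_isolation(w_train, w_refine_raw, w_test)

    for (target in targets) {
      n_classes <- if (target == "fe") 5L else 3L
      plan <- resample_plan(target, n_per_recording, plan_seed)
      bal_train <- balance_by_recording(w_train, plan)
      bal_refine <- balance_by_recording(w_refine_raw, plan)

      model <- build_model(n_classes,
                           seed = derive_seed(config$seed, "init", target, p))
      model <- train_initial(model, bal_train, config, norm = params)
      model <- refine(model, bal_refine, config, test_participant = p)
      pred <- predict_bins(model, w_test)
      truth <- window_labels(model, w_test)
      folds[[target]][[length(folds[[target]]) + 1L]] <-
        c(fold_metrics(truth, pred, n_classes, p, target),
          list(stop_epoch_initial = model$log$initial$stop_epoch,
               stop_epoch_refine = model$log$refine$stop_epoch))
      if (verbose) {
        f <- folds[[target]][[length(folds[[target]])]]
        message(sprintf(
          "fold P%d %s: acc %.3f kappa %.3f (%d test windows; epochs %d+%d)",
          p, target, f$accuracy, f$kappa, f$n_test_windows,
          f$stop_epoch_initial, f$stop_epoch_refine))
      }
    }
  }

  out <- list(targets = list(), participants = participants,
              n_per_recording = n_per_recording)
  for (target in targets) {
    out$targets[[target]] <- summarize_target(
      folds[[target]], if (target == "fe") 5L else 3L)
  }
  structure(out, class = "wp_eval_report")
}

#' @export
print.wp_eval_report <- function(x, ...) {
  cat("<wp_eval_report> ", length(x$participants), " folds\n", sep = "")
  for (target in names(x$targets)) {
    s <- x$targets[[target]]
    cat(sprintf("  %s: accuracy %.3f +/- %.3f, kappa %.3f +/- %.3f (%s)\n",
                toupper(target), s$mean_accuracy, s$se_accuracy,
                s$mean_kappa, s$se_kappa, s$kappa_label))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json`, per-target contingency CSVs, and a plain-text summary
#' with fold means, standard errors, row-normalized contingency tables and
#' within-1-bin rates.
#'
#' @param report A `wp_eval_report`.
#' @param dir Output directory.
#' @param extra Named list merged into the JSON report (e.g. config hash).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(participants = report$participants,
             n_per_recording = report$n_per_recording)
  txt <- c("Leave-one-subject-out evaluation", "")
  for (target in names(report$targets)) {
    s <- report$targets[[target]]
    js[[target]] <- list(
      mean_accuracy = s$mean_accuracy, se_accuracy = s$se_accuracy,
      mean_kappa = s$mean_kappa, se_kappa = s$se_kappa,
      kappa_label = s$kappa_label,
      within_1_bin = s$within_1_bin,
      contingency_counts = s$contingency_counts,
      contingency_row_norm = s$contingency_row_norm,
      folds = lapply(s$folds, function(f)
        f[c("test_participant", "n_test_windows", "accuracy", "kappa")])
    )
    utils::write.csv(s$contingency_counts,
                     file.path(dir, paste0("contingency_", target, ".csv")))
    txt <- c(txt,
             sprintf("%s: accuracy %.3f +/- %.3f, kappa %.3f +/- %.3f (%s)",
                     toupper(target), s$mean_accuracy, s$se_accuracy,
                     s$mean_kappa, s$se_kappa, s$kappa_label),
             "row-normalized contingency (true rows, predicted columns):",
             utils::capture.output(print(round(s$contingency_row_norm, 2))),
             sprintf("within-1-bin rates: %s",
                     paste(sprintf("%.2f", s$within_1_bin), collapse = " ")),
             "")
  }
  js <- c(js, extra)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(jp)
}
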