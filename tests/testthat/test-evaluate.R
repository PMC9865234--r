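# Agreement statistics and the LOSO report machinery.

# independent oracle: kappa from raw contingency counts, straight from the
# definition p_o = sum n_ii / n, p_e = sum (row_i * col_i) / n^2
kappa_bruteforce <- function(truth, pred, K) {
  n <- length(truth)
  tab <- matrix(0, K, K)
  for (i in seq_len(n)) tab[truth[i] + 1, pred[i] + 1] <- tab[truth[i] + 1, pred[i] + 1] + 1
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e == 1) return(1)
  (p_o - p_e) / (1 - p_e)
}

test_that("Cohen's kappa reproduces hand-computed and degenerate cases", {
  expect_equal(cohen_kappa(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(cohen_kappa(c(0, 1), c(1, 0)), -1)  # p_o = 0, p_e = 0.5
  expect_equal(cohen_kappa(rep(2, 5), rep(2, 5)), 1)  # degenerate marginals
  expect_error(cohen_kappa(0:2, 0:3), "length")
  expect_error(cohen_kappa(integer(0), integer(0)), "empty")
})

test_that("kappa matches the brute-force contingency oracle on small instances", {
  # all label pairs of length <= 6 over 3 classes, sampled densely
  set.seed(17)
  for (len in 1:6) {
    for (rep in 1:60) {
      truth <- sample(0:2, len, TRUE)
      pred <- sample(0:2, len, TRUE)
      expect_equal(cohen_kappa(truth, pred), kappa_bruteforce(truth, pred, 3),
                   tolerance = 1e-12)
    }
  }
})

test_that("kappa equals accuracy under uniform balanced marginals", {
  # with uniform marginals p_e = 1/K, and kappa = (p_o - 1/K)/(1 - 1/K);
  # construct a cyclic error pattern that keeps both marginals uniform
  truth <- rep(0:2, times = 12)
  pred <- truth
  pred[1:6] <- (truth[1:6] + 1) %% 3  # errors that preserve uniform marginals
  p_o <- mean(truth == pred)
  expect_equal(cohen_kappa(truth, pred), (p_o - 1/3) / (1 - 1/3),
               tolerance = 1e-12)
})

test_that("Landis-Koch labels follow the published thresholds", {
  expect_equal(landis_koch_label(0.41), "Moderate")
  expect_equal(landis_koch_label(0.28), "Fair")
  expect_equal(landis_koch_label(1.0), "Almost Perfect")
  expect_equal(landis_koch_label(-0.2), "Poor")
  expect_equal(landis_koch_label(0), "Slight")
  expect_equal(landis_koch_label(0.20), "Slight")
  expect_equal(landis_koch_label(0.60), "Moderate")
  expect_equal(landis_koch_label(0.80), "Substantial")
  expect_error(landis_koch_label(1.5), "\\[-1, 1\\]")
})

test_that("contingency tables count, normalize and validate", {
  expect_equal(contingency_table(c(0, 0, 1), c(0, 0, 1), 2),
               matrix(c(2, 0, 0, 1), 2, 2))
  set.seed(23)
  truth <- sample(0:4, 200, TRUE)
  pred <- sample(0:4, 200, TRUE)
  p <- contingency_table(truth, pred, 5, normalize = "row")
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-9)
  expect_error(contingency_table(c(0, 5), c(0, 1), 5), "out of range")

  # empty true class -> NaN row, not a division
  p2 <- wristposture:::row_normalize(contingency_table(c(0, 0), c(0, 1), 3))
  expect_true(all(is.nan(p2[2, ])))
})

test_that("within-k-bin rates match direct summation, including full span", {
  p <- diag(5)
  expect_equal(within_k_bins(p, 1), rep(1, 5))
  set.seed(29)
  p <- contingency_table(sample(0:4, 500, TRUE), sample(0:4, 500, TRUE), 5,
                         normalize = "row")
  expect_equal(within_k_bins(p, 4), rep(1, 5), tolerance = 1e-9)
  for (i in 1:5) {
    j <- which(abs(seq_len(5) - i) <= 1)
    expect_equal(within_k_bins(p, 1)[i], sum(p[i, j]))
  }
  expect_error(within_k_bins(matrix(0, 2, 3)), "square")
})

test_that("the fold-isolation audit passes disjoint sets and catches overlap", {
  w_train <- labelled_windows(runif(20), participant = 1, session = 1)
  w_ref <- labelled_windows(runif(20), participant = 2, session = 1)
  w_test <- labelled_windows(runif(20), participant = 2, session = 2)
  expect_true(audit_fold_isolation(w_train, w_ref, w_test))
  # same participant/session/recording/offsets in train and test -> overlap
  leak <- labelled_windows(runif(20), participant = 2, session = 2)
  expect_error(audit_fold_isolation(leak, w_ref, w_test), "fold isolation")
})

test_that("LOSO requires at least three participants", {
  cohort <- generate_cohort(2, tiny_sim_config(duration = 3))
  expect_error(loso_evaluate(cohort), "at least 3")
})

test_that("evaluation reports serialize with valid structure", {
  # build a minimal synthetic report via the summary path
  folds <- lapply(1:3, function(p) {
    set.seed(p)
    truth <- sample(0:4, 50, TRUE)
    pred <- ifelse(runif(50) < 0.6, truth, sample(0:4, 50, TRUE))
    wristposture:::fold_metrics(truth, pred, 5, p, "fe")
  })
  rep <- structure(list(targets = list(fe = wristposture:::summarize_target(folds, 5)),
                        participants = 1:3, n_per_recording = 250),
                   class = "wp_eval_report")
  expect_equal(rep$targets$fe$n_folds, 3)
  expect_equal(sum(rep$targets$fe$contingency_counts), 150)
  ok_rows <- rowSums(rep$targets$fe$contingency_counts) > 0
  expect_equal(rowSums(rep$targets$fe$contingency_row_norm)[ok_rows],
               rep(1, sum(ok_rows)), tolerance = 1e-9)

  d <- withr::local_tempdir()
  write_report(rep, d, extra = list(config_hash = "abc"))
  js <- jsonlite::read_json(file.path(d, "report.json"), simplifyVector = TRUE)
  expect_equal(js$config_hash, "abc")
  expect_equal(js$fe$mean_kappa, rep$targets$fe$mean_kappa, tolerance = 1e-12)
  expect_true(file.exists(file.path(d, "contingency_fe.csv")))
  expect_true(file.exists(file.path(d, "summary.txt")))
})
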