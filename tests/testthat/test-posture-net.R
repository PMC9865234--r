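# Convolutional classifier: construction, gradients, training protocol.

test_that("the valid-padding shape chain flattens to 1472", {
  # layer-shape arithmetic oracle: (12,100) -conv3x3-> (10,98) -pool->
  # (5,49) -conv3x3-> (3,47) -pool-> (1,23); 64 * 23 = 1472
  ref <- local({
    d <- c(12L, 100L)
    d <- d - 2L; d <- d %/% 2L; d <- d - 2L; d <- d %/% 2L
    64L * prod(d)
  })
  shapes <- cnn_shape_chain(5)
  expect_equal(shapes$flatten_len, ref)
  expect_equal(shapes$flatten_len, 1472L)
  expect_equal(shapes$conv1, c(10L, 98L, 32L))
  expect_equal(shapes$pool2, c(1L, 23L, 64L))
  expect_equal(cnn_shape_chain(3)$output, 3L)
})

test_that("model construction is seed-deterministic with the requested width", {
  m5 <- build_model(5, seed = 31)
  expect_equal(nrow(m5$weights$W4), 5L)
  expect_equal(dim(m5$weights$W3), c(4096L, 1472L))
  m5b <- build_model(5, seed = 31)
  expect_identical(m5$weights, m5b$weights)
  m5c <- build_model(5, seed = 32)
  expect_false(identical(m5$weights$W1, m5c$weights$W1))
  expect_error(build_model(1), "n_classes")
})

test_that("predictions are one label per window with unit-sum probabilities", {
  set.seed(41)
  w <- labelled_windows(runif(30, -40, 20), with_x = TRUE)
  m <- build_model(5, seed = 1)
  p <- predict_proba(m, w)
  expect_equal(dim(p), c(30L, 5L))
  expect_equal(rowSums(p), rep(1, 30), tolerance = 1e-6)
  bins <- predict_bins(m, w)
  expect_length(bins, 30)
  expect_true(all(bins %in% 0:4))
})

test_that("analytic gradients match finite differences along the gradient direction", {
  set.seed(5)
  X <- matrix(runif(16 * 1200), 16, 1200)
  y <- sample(0:4, 16, TRUE)
  m <- build_model(5, seed = 2)
  g <- wristposture:::cnn_grad_cpp(X, as.integer(y), m$weights, 5L)
  f <- function(w) wristposture:::cnn_loss_cpp(X, as.integer(y), w, 5L)
  h <- 3e-3
  for (group in list(c("W1", "b1", "W2", "b2"), c("W3", "b3", "W4", "b4"))) {
    d <- lapply(m$weights, function(x) x * 0)
    for (nm in group) d[[nm]] <- g[[nm]]
    nrm <- sqrt(sum(unlist(d)^2))
    wp <- m$weights; wm <- m$weights
    for (nm in group) {
      wp[[nm]] <- wp[[nm]] + h * d[[nm]] / nrm
      wm[[nm]] <- wm[[nm]] - h * d[[nm]] / nrm
    }
    ratio <- ((f(wp) - f(wm)) / (2 * h)) / nrm
    expect_equal(ratio, 1, tolerance = 0.05)
  }
})

test_that("a linearly separable toy problem is learned to >= 99% accuracy", {
  w <- separable_toy_windows()
  cfg <- train_config(initial = list(patience = 10L, max_epochs = 50L,
                                     learning_rate = 1e-3),
                      seed = 77)
  m <- build_model(5, seed = 3)
  m <- train_initial(m, w, cfg)
  expect_lte(m$log$initial$stop_epoch, 50L)
  pred <- predict_bins(m, w)
  expect_gte(mean(pred == w$fe_bin), 0.99)
})

test_that("training requires at least two classes", {
  w <- labelled_windows(rep(0, 50), with_x = TRUE)  # all bin 2
  expect_error(train_initial(build_model(5), w), "fewer than 2 classes")
})

test_that("a loss plateau stops training after exactly patience epochs", {
  # learning rate 0 freezes the monitor after the first epoch, so training
  # must stop at epoch 1 + patience with the epoch-1 weights retained
  w <- separable_toy_windows(n = 80)
  cfg <- train_config(initial = list(patience = 4L, max_epochs = 50L,
                                     learning_rate = 0),
                      refine = list(patience = 1L, max_epochs = 50L,
                                    learning_rate = 0),
                      seed = 8)
  m <- build_model(5, seed = 4)
  fit <- train_initial(m, w, cfg)
  expect_equal(fit$log$initial$stop_epoch, 1L + 4L)
  expect_equal(fit$log$initial$best_epoch, 1L)
  expect_equal(fit$log$initial$stop_reason, "early_stop")
  # weights pass through the trainer's single-precision representation
  expect_equal(fit$weights, m$weights, tolerance = 1e-6)
})

test_that("refinement guards against subject and session leakage", {
  w1 <- labelled_windows(runif(60, -40, 10), participant = 3, session = 1,
                         with_x = TRUE)
  w2 <- labelled_windows(runif(60, -40, 10), participant = 3, session = 2,
                         with_x = TRUE)
  m <- build_model(5, seed = 5)
  m$train_participants <- c(1, 2)
  cfg <- train_config(initial = list(patience = 1L, max_epochs = 1L,
                                     learning_rate = 1e-3), seed = 9)

  expect_error(refine(m, w2, cfg), "session 1")
  expect_error(refine(m, w1, cfg, test_participant = 4), "expected test participant")
  expect_error(refine(m, windows_concat(w1, labelled_windows(
    runif(10), participant = 9, session = 1, with_x = TRUE)), cfg),
    "single participant")
  m_leak <- m
  m_leak$train_participants <- c(1, 2, 3)
  expect_error(refine(m_leak, w1, cfg), "leakage")
})

test_that("refinement with zero learning rate leaves weights and predictions unchanged", {
  w_tr <- separable_toy_windows(n = 80, seed = 11)
  cfg0 <- train_config(initial = list(patience = 2L, max_epochs = 2L,
                                      learning_rate = 1e-3),
                       refine = list(patience = 1L, max_epochs = 5L,
                                     learning_rate = 1e-4),
                       seed = 10)
  m <- train_initial(build_model(5, seed = 6), w_tr, cfg0)
  pred_before <- predict_bins(m, w_tr)

  cfg_null <- train_config(initial = list(patience = 2L, max_epochs = 2L,
                                          learning_rate = 0),
                           refine = list(patience = 1L, max_epochs = 5L,
                                         learning_rate = 0),
                           seed = 10)
  w_ref <- labelled_windows(runif(50, -40, 10), participant = 9, session = 1,
                            with_x = TRUE)
  m2 <- refine(m, w_ref, cfg_null, test_participant = 9)
  expect_equal(m2$weights, m$weights, tolerance = 1e-6)
  expect_identical(predict_bins(m2, w_tr), pred_before)
})

test_that("model bundles round-trip through disk", {
  m <- build_model(3, seed = 12)
  m$train_participants <- c(1, 2)
  d <- withr::local_tempdir()
  save_model(m, d)
  m2 <- load_model(d)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$n_classes, 3L)
  expect_equal(m2$target, "ru")
})
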