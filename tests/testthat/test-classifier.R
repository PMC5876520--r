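test_that("sliding-window extraction counts and alignment", {
  f <- extract_features(random_stream(500, 1))
  labels <- rep_len(0:3, 500)
  w <- make_windows(f, labels, window_len = 100, stride = 1)
  expect_equal(dim(w$inputs), c(401, 100, 11))
  expect_equal(dim(w$targets), c(401, 100))

  w1 <- make_windows(extract_features(random_stream(100, 2)), rep(0, 100),
                     window_len = 100)
  expect_equal(dim(w1$inputs)[1], 1)

  w2 <- make_windows(extract_features(random_stream(103, 3)), rep(0, 103),
                     window_len = 100, stride = 2)
  expect_equal(w2$offsets, c(0, 2))

  # targets stay frame-aligned with inputs
  expect_equal(w$targets[5, ], labels[5:104])
  expect_equal(w$inputs[5, , ], unname(as.matrix(f[5:104, feature_cols])))

  expect_error(make_windows(f[1:50, ], labels[1:50], window_len = 100),
               "shorter than the window")
})

test_that("class weights are mean-normalized inverse frequencies", {
  expect_equal(class_weights(c(50, 50)), c(1, 1))
  expect_equal(class_weights(c(90, 10)), c(5 / 9, 5))
  expect_equal(class_weights(c(90, 10) * 10), class_weights(c(90, 10)))
  expect_equal(class_weights(c(10, 0, 30))[2], 0)
  expect_error(class_weights(c(0, 0)), "zero")
})

test_that("weighted cross-entropy matches closed forms and the oracle", {
  y <- one_hot(c(0L, 1L, 2L), 3)
  expect_equal(weighted_cce(y, y), -log(1))
  # uniform prediction, K = 4, alpha = 1: loss is log 4
  y4 <- one_hot(2L, 4)
  expect_equal(weighted_cce(y4, matrix(0.25, 1, 4)), log(4))
  # random instances against the straight-loop oracle
  set.seed(42)
  for (i in 1:100) {
    yt <- one_hot(sample(0:2, 5, TRUE), 3)
    yp <- matrix(rexp(15), 5, 3)
    yp <- yp / rowSums(yp)
    a <- runif(3, 0.1, 3)
    expect_equal(weighted_cce(yt, yp, a), oracle_wcce(yt, yp, a),
                 tolerance = 1e-12)
    # all-ones weights reduce to plain categorical cross-entropy
    expect_equal(weighted_cce(yt, yp), oracle_wcce(yt, yp, c(1, 1, 1)),
                 tolerance = 1e-12)
  }
})

test_that("network outputs are valid per-timestep distributions", {
  cfg <- classifier_config(num_classes = 12, window_len = 15,
                           dense_units = 8, gru_units = c(6L, 5L), seed = 2)
  cl <- seq_classifier(cfg)
  p0 <- predict_window(cl, matrix(0, 15, 11))
  expect_equal(dim(p0), c(15, 12))
  expect_equal(rowSums(p0), rep(1, 15), tolerance = 1e-5)
  x <- matrix(rnorm(15 * 11), 15, 11)
  p1 <- predict_window(cl, x)
  expect_true(all(p1 >= 0))
  expect_equal(rowSums(p1), rep(1, 15), tolerance = 1e-5)
  # inference is deterministic (dropout off)
  expect_identical(p1, predict_window(cl, x))
  # batch order does not affect per-window outputs
  xs <- array(rnorm(4 * 15 * 11), dim = c(4, 15, 11))
  pb <- predict_windows(cl, xs)
  perm <- c(3, 1, 4, 2)
  pb2 <- predict_windows(cl, xs[perm, , , drop = FALSE])
  expect_equal(pb2, pb[perm, , ], tolerance = 1e-12)
  expect_error(predict_window(cl, matrix(0, 14, 11)), "expected")
})

test_that("analytic gradients match central finite differences", {
  cfg <- classifier_config(num_classes = 4, window_len = 6, feature_dim = 3,
                           dense_units = 5, gru_units = c(4L, 3L),
                           dropout_rate = 0, seed = 3)
  cl <- seq_classifier(cfg)
  set.seed(7)
  X <- array(rnorm(2 * 3 * 6), dim = c(2, 3, 6)) # (batch, feature, time)
  Y <- matrix(sample(0:3, 12, TRUE), 2, 6)
  alpha <- c(1, 2, 0.5, 1.5)
  loss_at <- function(params) {
    motionseg:::cpp_net_train_batch(params, cl$running, X, Y, alpha, 0, 0.99,
                                    1L, FALSE)$loss
  }
  out <- motionseg:::cpp_net_train_batch(cl$params, cl$running, X, Y, alpha,
                                         0, 0.99, 1L, FALSE)
  eps <- 1e-6
  for (nm in names(cl$params)) {
    for (i in sample(length(cl$params[[nm]]), min(3, length(cl$params[[nm]])))) {
      pp <- cl$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- cl$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      numeric_grad <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      analytic <- as.numeric(out$grads[[nm]])[i]
      expect_equal(analytic, numeric_grad, tolerance = 1e-4,
                   info = paste(nm, i))
    }
  }
})

test_that("parameter count is independent of the window length", {
  mk <- function(L) seq_classifier(classifier_config(
    num_classes = 8, window_len = L, dense_units = 8, gru_units = c(6L, 5L)))
  expect_equal(n_params(mk(10)), n_params(mk(200)))
})

test_that("training reduces the weighted loss and is seed-reproducible", {
  fx <- tiny_trained()
  hist <- tidy(fx$classifier)
  expect_lt(tail(hist$loss, 1), hist$loss[1])
  expect_true(fx$classifier$trained)
  # per-frame training accuracy on a training recording is high
  rec <- fx$corpus$train[[1]]
  f <- standardize_features(extract_features(rec$stream),
                            fx$classifier$feature_stats)
  w <- make_windows(f, rec$labels, window_len = 40, stride = 40)
  p <- predict_windows(fx$classifier, w$inputs)
  pred <- apply(p, c(1, 2), which.max) - 1L
  expect_gt(mean(pred == w$targets), 0.9)
})

test_that("training is exactly reproducible under a fixed seed", {
  cfg <- classifier_config(num_classes = 4, window_len = 10, dense_units = 6,
                           gru_units = c(5L, 4L), epochs = 2, batch_size = 8,
                           seed = 17)
  f <- extract_features(random_stream(60, 2))
  labels <- rep_len(c(0L, 0L, 1L, 2L, 3L, 0L), 60)
  w <- make_windows(f, labels, window_len = 10, stride = 2)
  cl1 <- train_classifier(seq_classifier(cfg), w)
  cl2 <- train_classifier(seq_classifier(cfg), w)
  expect_identical(cl1$history, cl2$history)
  expect_identical(cl1$params, cl2$params)
})

test_that("checkpoint save/load reproduces predictions exactly", {
  fx <- tiny_trained()
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(fx$classifier, path)
  cl2 <- load_classifier(path)
  x <- matrix(rnorm(40 * 11), 40, 11)
  expect_equal(predict_window(cl2, x), predict_window(fx$classifier, x),
               tolerance = 1e-12)
  expect_equal(cl2$feature_stats, fx$classifier$feature_stats)
  expect_equal(cl2$alpha, fx$classifier$alpha)
})

test_that("glance and tidy summarize a fitted classifier", {
  fx <- tiny_trained()
  g <- glance(fx$classifier)
  expect_equal(g$num_classes, 6)
  expect_equal(g$epochs, 15)
  expect_equal(g$final_loss, tail(tidy(fx$classifier)$loss, 1))
})
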