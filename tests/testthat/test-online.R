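test_that("accumulator applies last-window-wins update semantics", {
  L <- 4; K <- 3
  acc <- accumulator(L, K)
  w1 <- matrix(1, L, K) / K
  acc <- acc_update(acc, w1)
  expect_equal(acc$t, L)
  expect_equal(acc$probs, w1)
  # second update overwrites rows 2..5, row 1 keeps its first estimate
  w2 <- matrix(rep(c(0.5, 0.3, 0.2), each = L), L, K)
  acc <- acc_update(acc, w2)
  expect_equal(acc$t, 5L)
  expect_equal(acc$probs[1, ], w1[1, ])
  expect_equal(acc$probs[2:5, ], w2)
  # re-applying identical estimates changes nothing on overlapping rows
  acc2 <- acc_update(acc, w2, t = 6L)
  expect_equal(acc2$probs[2:5, ], w2)
  expect_error(acc_update(acc, w2[1:3, ]), "must be")
  expect_error(acc_update(acc, w2, t = 5L), "advance")
})

test_that("replay: every sample's final estimate comes from the last window containing it", {
  set.seed(31)
  L <- 6; K <- 4; t_end <- 25
  # distinct window outputs so provenance is identifiable
  wins <- lapply(L:t_end, function(t) {
    p <- matrix(rexp(L * K), L, K)
    p / rowSums(p)
  })
  acc <- accumulator(L, K)
  for (i in seq_along(wins)) acc <- acc_update(acc, wins[[i]], t = L + i - 1L)
  # oracle: sample s (1-based) is covered by windows ending in s..s+L-1;
  # the last applied one ends at min(t_end, s + L - 1)
  for (s in 1:t_end) {
    t_last <- min(t_end, s + L - 1)
    row_in_window <- s - (t_last - L)
    expect_equal(acc$probs[s, ], wins[[t_last - L + 1]][row_in_window, ])
  }
})

test_that("finalized rows never change on later updates", {
  set.seed(13)
  L <- 5; K <- 3
  acc <- accumulator(L, K)
  snapshots <- list()
  for (t in L:30) {
    p <- matrix(rexp(L * K), L, K); p <- p / rowSums(p)
    acc <- acc_update(acc, p, t = t)
    if (t - L >= 1) {
      # rows with index <= t - L are final
      if (length(snapshots) > 0) {
        prev <- snapshots[[length(snapshots)]]
        n_final <- min(nrow(prev), acc$t - L)
        expect_equal(acc$probs[seq_len(n_final), ],
                     prev[seq_len(n_final), ])
      }
    }
    snapshots[[length(snapshots) + 1]] <- acc$probs
  }
})

test_that("discretize takes the row argmax with low-index tie-breaking", {
  expect_equal(discretize(acc_from_probs(matrix(c(0.1, 0.7, 0.2), 1))), 1L)
  expect_equal(discretize(acc_from_probs(matrix(c(0.5, 0.5), 1))), 0L)
  expect_equal(discretize(acc_from_probs(matrix(1 / 3, 4, 3))), rep(0L, 4))
})

test_that("lcss agrees with the recursive oracle and yields a valid alignment", {
  set.seed(17)
  for (i in 1:100) {
    a <- sample(0:4, sample(1:12, 1), replace = TRUE)
    b <- sample(0:4, sample(1:12, 1), replace = TRUE)
    r <- lcss(a, b)
    expect_equal(r$length, oracle_lcss(a, b))
    expect_equal(length(r$a_pos), r$length)
    expect_true(all(diff(r$b_pos) > 0))
    expect_equal(a[r$a_pos], b[r$b_pos])
  }
})

# build an accumulator whose discretized sequence equals `states`
acc_from_states <- function(states, K, peak = 0.9) {
  n <- length(states)
  p <- matrix((1 - peak) / (K - 1), n, K)
  p[cbind(seq_len(n), states + 1L)] <- peak
  acc_from_probs(p, window_len = n)
}

test_that("exact detection requires the full boundary pattern in order", {
  m <- kick_model()
  K <- n_classes(m)
  good <- c(0, 0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 0, 0)
  det <- detect_motion(acc_from_states(good, K), m)
  expect_true(det$detected)
  expect_true(all(diff(det$boundary_frames) > 0))
  expect_equal(det$boundary_frames, c(2, 4, 6, 8, 10, 12))
  expect_gte(det$detection_time, max(det$boundary_frames))

  # LS7 (class 7) missing entirely: no exact match
  missing7 <- c(0, 0, 1, 2, 3, 4, 5, 6, 8, 9, 10, 11, 0)
  det2 <- detect_motion(acc_from_states(missing7, K), m)
  expect_false(det2$detected)
  # ...but the tolerant detector accepts 5 of 6 boundaries
  det3 <- detect_motion(acc_from_states(missing7, K), m, mode = "lcss",
                        min_ratio = 0.8)
  expect_true(det3$detected)
  expect_equal(oracle_lcss(boundary_states(m),
                           missing7[missing7 != 0]), 5L)
  # frames before `after` are consumed and cannot re-fire
  det4 <- detect_motion(acc_from_states(good, K), m, after = 12L)
  expect_false(det4$detected)
})

test_that("segmentation picks unconflicted peaks directly", {
  m <- tiny_model(2) # boundary classes 1, 3, 5
  K <- n_classes(m)
  p <- matrix(0.01, 12, K)
  p[3, 2] <- 0.9   # class 1 peaks at frame 2
  p[6, 4] <- 0.9   # class 3 peaks at frame 5
  p[10, 6] <- 0.9  # class 5 peaks at frame 9
  seg <- segment_motion(acc_from_probs(p, 12), m)
  expect_equal(seg$boundaries$frame, c(2, 5, 9))
  expect_equal(seg$phases$start_frame, c(2, 5))
  expect_equal(seg$phases$end_frame, c(5, 9))
})

test_that("segmentation DP equals exhaustive search on random instances", {
  set.seed(23)
  for (i in 1:200) {
    n_b <- sample(2:4, 1)
    m <- tiny_model(n_b - 1)
    K <- n_classes(m)
    n <- sample(n_b:15, 1)
    p <- matrix(rexp(n * K), n, K)
    p <- p / rowSums(p)
    seg <- segment_motion(acc_from_probs(p, n), m)
    oracle <- oracle_segment(p, boundary_states(m))
    expect_equal(seg$boundaries$frame, oracle$frames)
    expect_equal(seg$log_score, oracle$score, tolerance = 1e-9)
    expect_true(all(diff(seg$boundaries$frame) > 0))
  }
})

test_that("uniform probabilities segment to the lexicographically smallest tuple", {
  m <- tiny_model(2)
  p <- matrix(1 / 6, 10, 6)
  seg <- segment_motion(acc_from_probs(p, 10), m)
  expect_equal(seg$boundaries$frame, c(0, 1, 2))
})

test_that("segmentation rejects a search range that cannot hold all boundaries", {
  m <- tiny_model(2)
  p <- matrix(1 / 6, 10, 6)
  expect_error(segment_motion(acc_from_probs(p, 10), m, search_range = c(0, 1)),
               "search range shorter")
})

test_that("evaluation implements the detected-only error protocol", {
  truth <- tibble::tibble(
    recording = rep(paste0("r", 1:5), each = 2),
    label = rep(c("B1", "B2"), 5),
    frame = rep(c(10L, 20L), 5)
  )
  # r5 undetected; r1 has errors (2, 1), others perfect
  est <- tibble::tibble(
    recording = rep(paste0("r", 1:4), each = 2),
    label = rep(c("B1", "B2"), 4),
    frame = c(12L, 19L, rep(c(10L, 20L), 3))
  )
  ev <- evaluate_segmentation(est, truth)
  expect_equal(ev$detection_rate, 0.8)
  expect_equal(ev$n_detected, 4)
  expect_equal(ev$per_boundary$mean_abs_error, c(2, 1) / 4)
  expect_equal(ev$per_boundary$n, c(4L, 4L))
  # perfect estimates: rate 1, zero error
  ev2 <- evaluate_segmentation(truth, truth)
  expect_equal(ev2$detection_rate, 1)
  expect_true(all(ev2$per_boundary$mean_abs_error == 0))
  expect_error(
    evaluate_segmentation(dplyr::mutate(est, recording = "zzz"), truth),
    "absent from truth"
  )
  g <- glance(ev)
  expect_equal(g$mean_abs_error, (2 + 1) / 8)
})

test_that("streaming detects one embedded motion once, none on clutter", {
  fx <- tiny_trained()
  rec <- fx$corpus$test[[1]]
  res <- run_stream(rec$stream, fx$classifier, fx$model)
  expect_equal(length(res), 1)
  truth <- labels_to_boundaries(rec$labels, fx$model)
  expect_lt(mean(abs(res[[1]]$boundaries$frame - truth$frame)), 5)
  expect_gte(res[[1]]$detection_time, max(res[[1]]$boundaries$frame))

  # pure none-state clutter must not fire
  set.seed(4)
  sig <- fx$spec$signatures
  t_len <- 120
  clutter <- tibble::tibble(
    frame = 0:(t_len - 1),
    ax = rnorm(t_len, sig$ax[1], 0.08), ay = rnorm(t_len, sig$ay[1], 0.08),
    az = rnorm(t_len, sig$az[1], 0.08), gx = rnorm(t_len, sig$gx[1], 12),
    gy = rnorm(t_len, sig$gy[1], 12), gz = rnorm(t_len, sig$gz[1], 12)
  )
  expect_length(run_stream(clutter, fx$classifier, fx$model), 0)

  # two well-separated motions in one stream yield two ordered results
  rec2 <- fx$corpus$test[[2]]
  both <- dplyr::bind_rows(rec$stream, rec2$stream)
  both$frame <- seq_len(nrow(both)) - 1L
  res2 <- run_stream(both, fx$classifier, fx$model)
  expect_equal(length(res2), 2)
  expect_lt(max(res2[[1]]$boundaries$frame), min(res2[[2]]$boundaries$frame))

  expect_error(run_stream(rec$stream[1:10, ], fx$classifier, fx$model),
               "shorter than one window")
})
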