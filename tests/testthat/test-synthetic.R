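test_that("generation is seed-deterministic", {
  spec <- synthetic_spec(kick_model())
  r1 <- generate_recording(spec, seed = 11)
  r2 <- generate_recording(spec, seed = 11)
  expect_identical(r1, r2)
  r3 <- generate_recording(spec, seed = 12)
  expect_false(identical(r1$stream, r3$stream))
  # byte-identical CSV output for the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(r1$stream, p1)
  write_imu_csv(r2$stream, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("label sequence follows the state pattern with single-frame boundaries", {
  model <- kick_model()
  spec <- synthetic_spec(model)
  for (seed in 1:5) {
    rec <- generate_recording(spec, seed = seed)
    runs <- rle(rec$labels)
    inner <- runs$values[runs$values != 0]
    expect_equal(inner, state_pattern(model))
    bnd_lengths <- runs$lengths[runs$values %in% boundary_states(model)]
    expect_true(all(bnd_lengths == 1))
    perf_lengths <- runs$lengths[runs$values %in%
                                   which(model$states$role == "performing")]
    expect_true(all(perf_lengths >= spec$phase_duration_range[1]))
    expect_true(all(perf_lengths <= spec$phase_duration_range[2]))
    # boundaries table points at the labeled boundary frames
    expect_equal(rec$labels[rec$boundaries$frame + 1],
                 boundary_states(model))
    # roughly five seconds at 100 Hz
    expect_gt(nrow(rec$stream), 200)
    expect_lt(nrow(rec$stream), 800)
  }
})

test_that("noise-free constant signatures give piecewise-constant channels", {
  model <- tiny_model(2)
  sig <- default_signatures(model)
  sig$amp <- 0
  spec <- synthetic_spec(model, signatures = sig,
                         noise_sd = rep(0, 6))
  rec <- generate_recording(spec, seed = 3)
  # within every labeled run the channels are constant; breakpoints only at
  # label changes
  changes <- which(diff(rec$stream$ax) != 0 | diff(rec$stream$gx) != 0)
  label_changes <- which(diff(rec$labels) != 0)
  expect_equal(changes, label_changes)
})

test_that("streams respect sensor ranges, clipping extremes with a warning", {
  model <- tiny_model(1)
  sig <- default_signatures(model)
  spec <- synthetic_spec(model, signatures = sig)
  rec <- generate_recording(spec, seed = 2)
  expect_true(all(abs(as.matrix(rec$stream[, c("ax", "ay", "az")])) <= 16))
  expect_true(all(abs(as.matrix(rec$stream[, c("gx", "gy", "gz")])) <= 2000))
  sig$az[2] <- 40 # absurd 40 g boundary signature
  sig$ax[3] <- 40
  spec_hot <- synthetic_spec(model, signatures = sig, noise_sd = rep(0, 6))
  expect_warning(rec_hot <- generate_recording(spec_hot, seed = 2), "clipping")
  expect_true(all(abs(rec_hot$stream$ax) <= 16))
})

test_that("the frame-labeling task is feasible for a signature-nearest classifier", {
  model <- kick_model()
  spec <- synthetic_spec(model)
  # noise is small relative to the separation of the state signatures
  sig <- as.matrix(spec$signatures[, c("ax", "ay", "az", "gx", "gy", "gz")])
  sig_n <- sig %*% diag(rep(c(1, 1 / 100), c(3, 3)))
  dmin <- min(stats::dist(sig_n))
  noise_n <- sqrt(sum((spec$noise_sd * rep(c(1, 1 / 100), c(3, 3)))^2))
  expect_lt(noise_n, dmin / 2)
  acc <- vapply(1:10, function(seed) {
    rec <- generate_recording(spec, seed = seed)
    mean(nearest_signature_labels(rec$stream, spec) == rec$labels)
  }, numeric(1))
  expect_gt(mean(acc), 0.95)
})

test_that("corpus split is per recording with per-recording randomness", {
  spec <- synthetic_spec(tiny_model(2), phase_duration_range = c(5L, 15L),
                         context_range = c(10L, 30L))
  corpus <- generate_corpus(spec, 10, train_fraction = 0.8, seed = 21)
  expect_length(corpus$train, 8)
  expect_length(corpus$test, 2)
  expect_equal(sort(corpus$manifest$id),
               sort(c(vapply(corpus$train, `[[`, "", "id"),
                      vapply(corpus$test, `[[`, "", "id"))))
  expect_false(anyDuplicated(corpus$manifest$seed) > 0)
  streams <- lapply(c(corpus$train, corpus$test), `[[`, "stream")
  for (i in 2:length(streams)) {
    expect_false(identical(streams[[1]], streams[[i]]))
  }
  expect_error(generate_corpus(spec, 10, train_fraction = 1), "degenerate")
  # reproducibility of the whole corpus
  corpus2 <- generate_corpus(spec, 10, train_fraction = 0.8, seed = 21)
  expect_identical(corpus$manifest, corpus2$manifest)
  expect_identical(corpus$train[[1]]$stream, corpus2$train[[1]]$stream)
})

test_that("boundary labels are rare: the imbalance the weighted loss addresses", {
  model <- kick_model()
  spec <- synthetic_spec(model)
  corpus <- generate_corpus(spec, 10, seed = 8)
  labels <- unlist(lapply(c(corpus$train, corpus$test), `[[`, "labels"))
  counts <- tabulate(labels + 1L, nbins = n_classes(model))
  bnd <- counts[boundary_states(model) + 1L]
  perf <- counts[setdiff(seq_len(11), boundary_states(model)) + 1L]
  expect_equal(bnd, rep(10L, 6)) # exactly one frame per recording each
  expect_true(all(perf > 5 * max(bnd)))
  w <- class_weights(counts)
  expect_true(all(w[boundary_states(model) + 1L] >
                    max(w[-(boundary_states(model) + 1L)])))
})
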