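#' Fit the sequence classifier to a set of labeled recordings
#'
#' The end-to-end training path: extracts the 11-element features of every
#' training recording, fits per-column standardization statistics on the
#' training data only, slices each standardized recording into
#' `window_len`-frame windows at the given stride, pools the windows, computes
#' inverse-frequency class weights from the pooled per-frame labels, and
#' trains the network. The fitted standardization statistics and class
#' weights travel with the returned classifier, so prediction and streaming
#' use exactly the training-time transform.
#'
#' @param recordings List of recordings, each a list with `stream` (tibble
#'   `frame, ax..gz`) and `labels` (integer per-frame class indices).
#' @param model The [motion_model()] the labels refer to.
#' @param config A [classifier_config()]; `NULL` uses defaults with
#'   `num_classes = n_classes(model)`.
#' @param stride Sliding-window stride (frames) for training-set extraction.
#' @param standardize Fit and apply per-column z-scoring (recommended: the
#'   features mix g and deg/s scales).
#' @param verbose Print per-epoch loss.
#' @return A trained `seq_classifier` with `feature_stats` attached.
#' @export
fit_motion_classifier <- function(recordings, model, config = NULL,
                                  stride = 1L, standardize = TRUE,
                                  verbose = FALSE) {
  stopifnot(length(recordings) >= 1)
  config <- config %||% classifier_config(num_classes = n_classes(model))
  if (config$num_classes != n_classes(model)) {
    abort("config num_classes does not match the motion model")
  }
  feats <- lapply(recordings, function(r) extract_features(r$stream))
  stats <- if (standardize) feature_stats(dplyr::bind_rows(feats)) else NULL
  sets <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    f <- standardize_features(feats[[i]], stats)
    sets[[i]] <- make_windows(f, recordings[[i]]$labels,
                              window_len = config$window_len, stride = stride)
  }
  windows <- combine_window_sets(sets)
  classifier <- seq_classifier(config)
  classifier <- train_classifier(classifier, windows, verbose = verbose)
  classifier$feature_stats <- stats
  classifier
}

#' Detect and segment every recording of a test set
#'
#' Feeds each recording through [run_stream()] as if it arrived on-line and
#' collects the first detected motion per recording into a boundary-estimate
#' table ready for [evaluate_segmentation()].
#'
#' @param recordings List of recordings (`stream`, `labels`, optional `id`).
#' @param classifier A trained `seq_classifier`.
#' @param model The [motion_model()].
#' @param stride,horizon,mode,min_ratio,margin Streaming and detector
#'   settings, see [run_stream()].
#' @return List with `est` (tibble `recording`, `label`, `frame`,
#'   `prob`) holding one row per boundary of each detected recording, and
#'   `results` (per-recording list of `motion_segmentation`).
#' @export
detect_corpus <- function(recordings, classifier, model, stride = 1L,
                          horizon = NULL, mode = c("exact", "lcss"),
                          min_ratio = 0.8, margin = 20L) {
  mode <- match.arg(mode)
  ids <- vapply(seq_along(recordings), function(i) {
    recordings[[i]]$id %||% sprintf("rec%04d", i)
  }, character(1))
  results <- vector("list", length(recordings))
  est <- list()
  for (i in seq_along(recordings)) {
    res <- run_stream(recordings[[i]]$stream, classifier, model,
                      stride = stride, horizon = horizon, mode = mode,
                      min_ratio = min_ratio, margin = margin)
    results[[i]] <- res
    if (length(res) > 0) {
      b <- res[[1]]$boundaries
      est[[length(est) + 1]] <- tibble::tibble(
        recording = ids[i], label = b$label, frame = b$frame, prob = b$prob
      )
    }
  }
  est <- if (length(est) > 0) dplyr::bind_rows(est) else
    tibble::tibble(recording = character(), label = character(),
                   frame = integer(), prob = numeric())
  list(est = est, results = results, ids = ids)
}

#' Ground-truth boundary table for a set of recordings
#' @param recordings List of recordings with `labels` (and optional `id`).
#' @param model The [motion_model()].
#' @return Tibble `recording`, `label`, `frame`.
#' @export
corpus_truth <- function(recordings, model) {
  dplyr::bind_rows(lapply(seq_along(recordings), function(i) {
    b <- labels_to_boundaries(recordings[[i]]$labels, model)
    tibble::tibble(recording = recordings[[i]]$id %||% sprintf("rec%04d", i),
                   label = b$label, frame = b$frame)
  }))
}

#' Scaled end-to-end detection and segmentation experiment
#'
#' The package's reference experiment: generate a seeded corpus of synthetic
#' five-phase recordings, train the sequence classifier on the training split,
#' stream every held-out recording through on-line detection and
#' segmentation, and score detections and boundary errors against the
#' generator's ground truth. Defaults are sized for a single CPU: 150
#' recordings (120 train / 30 test), training windows at stride 8, 8 epochs.
#'
#' @param seed Master seed for corpus generation and training.
#' @param n_recordings Corpus size.
#' @param train_fraction Recording-level training fraction.
#' @param epochs Training epochs.
#' @param train_stride Sliding-window stride for training-set extraction.
#' @param stream_stride Classifier invocation stride during streaming.
#' @param model Motion model; default the bundled five-phase kicking model.
#' @param verbose Print progress.
#' @return List with `evaluation` (a `segmentation_evaluation`),
#'   `detection_rate`, `interior_mae` (mean absolute error over the interior
#'   boundaries, i.e. excluding the motion's first and last), `classifier`,
#'   `est`, `truth`.
#' @export
run_reference_experiment <- function(seed = 1L, n_recordings = 150L,
                                     train_fraction = 0.8, epochs = 8L,
                                     train_stride = 8L, stream_stride = 1L,
                                     model = NULL, verbose = FALSE) {
  model <- model %||% read_motion_model(
    system.file("extdata", "soccer_kick.yaml", package = "motionseg"))
  spec <- synthetic_spec(model)
  corpus <- generate_corpus(spec, n_recordings, train_fraction = train_fraction,
                            seed = seed)
  cfg <- classifier_config(num_classes = n_classes(model), epochs = epochs,
                           seed = as.integer(seed))
  classifier <- fit_motion_classifier(corpus$train, model, config = cfg,
                                      stride = train_stride, verbose = verbose)
  # the detection horizon must cover the longest motion the generator can
  # produce (all boundary frames must fit in one scan window); the maximum
  # span is known from the spec's duration range
  max_span <- model$n_phases * spec$phase_duration_range[2] +
    model$n_phases + 1L
  det <- detect_corpus(corpus$test, classifier, model, stride = stream_stride,
                       horizon = max_span + 50L)
  truth <- corpus_truth(corpus$test, model)
  ev <- evaluate_segmentation(det$est, truth)

  interior_labels <- head(tail(model$states$label[model$states$role == "boundary"], -1), -1)
  pb <- ev$per_boundary
  interior <- pb[pb$label %in% interior_labels, ]
  interior_mae <- if (nrow(interior) > 0) {
    sum(interior$mean_abs_error * interior$n) / sum(interior$n)
  } else {
    NA_real_
  }
  list(evaluation = ev, detection_rate = ev$detection_rate,
       interior_mae = interior_mae, classifier = classifier,
       est = det$est, truth = truth)
}
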