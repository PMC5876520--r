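#' On-line accumulator of per-sample state probabilities
#'
#' The classifier only ever sees a fixed-length window of `L` frames, but a
#' motion can be longer than one window. The accumulator stitches successive
#' window outputs into a growing per-sample probability record: each update
#' overwrites the estimates of the `L` most recent samples, so a sample's
#' final estimate is the one from the *last* window that contained it, and
#' estimates of samples older than `t - L` are final and never change again.
#'
#' @param window_len Window length `L` in frames.
#' @param num_classes `K`.
#' @return An `accumulator` object with fields `probs` (`t x K` matrix, one
#'   row per consumed sample), `window_len`, `t` (samples consumed).
#' @export
accumulator <- function(window_len, num_classes) {
  structure(list(
    probs = matrix(numeric(0), 0, num_classes),
    window_len = as.integer(window_len), t = 0L
  ), class = "accumulator")
}

#' Apply one classifier output window to the accumulator
#'
#' @param acc An [accumulator()].
#' @param window_probs `L x K` probability matrix covering samples
#'   `t - L + 1 .. t`.
#' @param t Sample count after this update (1-based). Defaults to `L` on the
#'   first update and `t + 1` afterwards (one new sample per update); larger
#'   strides up to `L` are allowed.
#' @return The updated accumulator.
#' @export
acc_update <- function(acc, window_probs, t = NULL) {
  stopifnot(inherits(acc, "accumulator"))
  window_probs <- as.matrix(window_probs)
  L <- acc$window_len
  if (nrow(window_probs) != L || ncol(window_probs) != ncol(acc$probs)) {
    abort(paste0("window output must be ", L, " x ", ncol(acc$probs)))
  }
  t <- as.integer(t %||% (if (acc$t == 0L) L else acc$t + 1L))
  if (t < L) abort("update ends before one full window of samples")
  if (t <= acc$t || t > acc$t + L) {
    abort("updates must advance by 1..L samples")
  }
  if (t > nrow(acc$probs)) {
    acc$probs <- rbind(acc$probs, matrix(0, t - nrow(acc$probs), ncol(acc$probs)))
  }
  acc$probs[(t - L + 1):t, ] <- window_probs
  acc$t <- t
  acc
}

#' Per-sample class indices from accumulated probabilities
#'
#' Row-wise argmax; ties break toward the lower class index (so an
#' uninformative uniform row is read as the none state).
#'
#' @param acc An [accumulator()], or a bare probability matrix.
#' @return Integer vector of 0-based class indices, one per sample.
#' @export
discretize <- function(acc) {
  probs <- if (inherits(acc, "accumulator")) acc$probs else as.matrix(acc)
  if (nrow(probs) == 0) abort("empty accumulator")
  max.col(probs, ties.method = "first") - 1L
}

#' Longest common subsequence length (and one optimal alignment)
#'
#' Classic quadratic DP on two discrete sequences; used by the tolerant
#' detector to match the model's boundary pattern against the discretized
#' state estimates. The traceback prefers the latest possible match positions
#' in `b` (it walks from the end), which anchors detection at the most recent
#' occurrence.
#'
#' @param a,b Integer vectors.
#' @return List with `length`, `a_pos` and `b_pos`: the positions in `a` and
#'   `b` matched in one optimal alignment (both increasing).
#' @export
lcss <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) {
    return(list(length = 0L, a_pos = integer(), b_pos = integer()))
  }
  d <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- if (a[i] == b[j]) d[i, j] + 1L
                         else max(d[i, j + 1], d[i + 1, j])
    }
  }
  i <- n; j <- m; a_pos <- integer(0); b_pos <- integer(0)
  while (i > 0 && j > 0) {
    if (a[i] == b[j] && d[i + 1, j + 1] == d[i, j] + 1L) {
      a_pos <- c(i, a_pos); b_pos <- c(j, b_pos); i <- i - 1; j <- j - 1
    } else if (d[i, j + 1] >= d[i + 1, j]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(length = d[n + 1, m + 1], a_pos = a_pos, b_pos = b_pos)
}

#' Detect a modeled motion in the accumulated state sequence
#'
#' Scans the most recent `horizon` frames of the discretized state estimates
#' backwards for the model's boundary-state pattern. `mode = "exact"` requires
#' every boundary state to appear in temporal order; `mode = "lcss"` tolerates
#' missing or mislabeled boundaries, accepting when the longest common
#' subsequence between pattern and estimates covers at least `min_ratio` of
#' the pattern. Frames at or before `after` are ignored, which is how a
#' completed match is consumed so one performance fires one detection.
#'
#' @param acc An [accumulator()].
#' @param model A [motion_model()].
#' @param horizon How many recent frames to scan (default `3 * L`).
#' @param mode `"exact"` or `"lcss"`.
#' @param min_ratio LCSS acceptance threshold (fraction of the pattern).
#' @param after 0-based frame index; only frames strictly later are searched.
#' @return A list: `detected` (flag), and when detected `boundary_frames`
#'   (0-based, strictly increasing, one per matched boundary state),
#'   `detection_time` (frame at which the pattern completed), `score` (mean
#'   probability of the matched boundary states).
#' @export
detect_motion <- function(acc, model, horizon = NULL, mode = c("exact", "lcss"),
                          min_ratio = 0.8, after = -1L) {
  stopifnot(inherits(acc, "accumulator"), inherits(model, "motion_model"))
  mode <- match.arg(mode)
  t <- acc$t
  if (t < 1) abort("empty accumulator")
  horizon <- as.integer(horizon %||% (3L * acc$window_len))
  if (horizon > t) horizon <- t
  pattern <- boundary_states(model)
  lo <- max(t - horizon + 1L, after + 2L) # 1-based row of first searchable frame
  hi <- t
  no <- list(detected = FALSE)
  if (hi - lo + 1L < length(pattern)) return(no)
  d <- discretize(acc)[lo:hi]

  if (mode == "exact") {
    # reverse greedy: latest occurrence of the last boundary, then latest
    # occurrence of the previous one before it, and so on
    pos <- integer(length(pattern))
    j <- length(d) + 1L
    for (k in rev(seq_along(pattern))) {
      cand <- which(d[seq_len(j - 1L)] == pattern[k])
      if (length(cand) == 0) return(no)
      j <- max(cand)
      pos[k] <- j
    }
    frames <- lo - 1L + pos - 1L # 0-based
    matched <- seq_along(pattern)
  } else {
    al <- lcss(pattern, d)
    if (al$length < min_ratio * length(pattern)) return(no)
    frames <- lo - 1L + al$b_pos - 1L
    matched <- al$a_pos
  }
  score <- mean(acc$probs[cbind(frames + 1L, pattern[matched] + 1L)])
  list(detected = TRUE, boundary_frames = frames, detection_time = t - 1L,
       score = score)
}

#' Localize every boundary state by constrained maximum-probability search
#'
#' Given accumulated state probabilities and a detected motion, finds the
#' temporal index of each boundary state: the set of frames, one per boundary
#' state and strictly increasing in time, that maximizes the summed
#' log-probability of the boundary states at their assigned frames. The
#' unconstrained per-state argmax satisfies this when the argmaxes are already
#' ordered; when they conflict, the dynamic program restores the ordering
#' constraint globally. Ties resolve to the lexicographically smallest frame
#' tuple.
#'
#' @param acc An [accumulator()] (or bare `t x K` probability matrix).
#' @param model A [motion_model()].
#' @param search_range 0-based inclusive frame interval `c(lo, hi)` to search
#'   (default: everything accumulated).
#' @return A `motion_segmentation` object: list with `boundaries` (tibble:
#'   `label`, `class_index`, `frame`, `prob`), `phases` (tibble: `phase`,
#'   `start_frame`, `end_frame`), and `log_score`.
#' @export
segment_motion <- function(acc, model, search_range = NULL) {
  probs <- if (inherits(acc, "accumulator")) acc$probs else as.matrix(acc)
  stopifnot(inherits(model, "motion_model"))
  bnd <- boundary_states(model)
  m <- length(bnd)
  search_range <- as.integer(search_range %||% c(0L, nrow(probs) - 1L))
  lo <- search_range[1]; hi <- search_range[2]
  stopifnot(lo >= 0, hi < nrow(probs))
  n <- hi - lo + 1L
  if (n < m) abort("search range shorter than the number of boundary states")
  lp <- log(pmax(probs[(lo + 1):(hi + 1), bnd + 1L, drop = FALSE], 1e-12))

  # suffix DP: g[j, k] = best score of boundaries k..m with boundary k at
  # frame j; best_from[j, k] = max over j' >= j of g[j', k]
  g <- matrix(-Inf, n, m)
  best_from <- matrix(-Inf, n + 1L, m) # best_from[j, k] = max_{j' >= j} g[j', k]
  g[, m] <- lp[, m]
  best_from[seq_len(n), m] <- rev(cummax(rev(g[, m])))
  if (m > 1) {
    for (k in (m - 1):1) {
      if (n > 1) {
        g[seq_len(n - 1L), k] <- lp[seq_len(n - 1L), k] + best_from[2:n, k + 1L]
      }
      best_from[seq_len(n), k] <- rev(cummax(rev(g[, k])))
    }
  }
  # greedy traceback: smallest frame achieving the remaining optimum at each
  # step, which yields the lexicographically smallest optimal tuple; the
  # equality is exact because best_from is a running max of the same values
  b <- integer(m)
  prev <- 0L
  for (k in seq_len(m)) {
    target <- best_from[prev + 1L, k]
    j <- prev + 1L
    while (g[j, k] != target) {
      j <- j + 1L
      if (j > n) abort("internal error: segmentation traceback failed")
    }
    b[k] <- j
    prev <- j
  }
  frames <- lo + b - 1L

  labels <- model$states$label[model$states$role == "boundary"]
  boundaries <- tibble::tibble(
    label = labels, class_index = bnd, frame = frames,
    prob = probs[cbind(frames + 1L, bnd + 1L)]
  )
  phases <- tibble::tibble(
    phase = model$phases$phase,
    start_frame = frames[-m],
    end_frame = frames[-1]
  )
  structure(list(boundaries = boundaries, phases = phases,
                 log_score = best_from[1, 1], model_name = model$name),
            class = "motion_segmentation")
}

#' @export
print.motion_segmentation <- function(x, ...) {
  cat("<motion_segmentation> ", x$model_name, "\n", sep = "")
  print(x$boundaries)
  invisible(x)
}

#' @export
tidy.motion_segmentation <- function(x, ...) x$boundaries

#' Run the full on-line detection and segmentation loop over one recording
#'
#' Emulates on-line operation on a recorded stream: features are extracted
#' (the feature map is causal), standardized with the classifier's stored
#' training statistics, and the trailing `L`-frame window is classified as
#' each new sample arrives (every `stride` samples). Window outputs are
#' accumulated, detection is attempted after every update, and each detected
#' motion is segmented and emitted. A refractory rule consumes the matched
#' span: later detections must lie strictly after the previous motion's last
#' boundary frame, so one performance yields exactly one result.
#'
#' @param stream IMU stream data frame (columns `ax..gz`).
#' @param classifier A trained `seq_classifier` (with `feature_stats` set by
#'   [fit_motion_classifier()], or `NULL` for raw features).
#' @param model The [motion_model()] to detect.
#' @param stride Samples between classifier invocations (1 = every sample).
#' @param horizon Detection scan depth in frames (default `3 * L`).
#' @param mode,min_ratio Detector settings, see [detect_motion()].
#' @param margin Extra frames around the matched span handed to the
#'   segmentation search.
#' @return List of `motion_segmentation` results in temporal order, each with
#'   a `detection_time` element added.
#' @export
run_stream <- function(stream, classifier, model, stride = 1L, horizon = NULL,
                       mode = c("exact", "lcss"), min_ratio = 0.8,
                       margin = 20L) {
  mode <- match.arg(mode)
  cfg <- classifier$config
  L <- cfg$window_len
  t_len <- nrow(stream)
  if (t_len < L) abort(paste0("stream (", t_len, " samples) shorter than one window (", L, ")"))

  feats <- extract_features(stream)
  feats <- standardize_features(feats, classifier$feature_stats)
  x <- as.matrix(feats[, feature_cols])

  ends <- seq(L, t_len, by = as.integer(stride)) # 1-based window end samples
  n_win <- length(ends)
  # batch all window forward passes, then replay updates sequentially
  probs_list <- vector("list", n_win)
  batch <- 256L
  for (bs in seq(1L, n_win, by = batch)) {
    idx <- bs:min(bs + batch - 1L, n_win)
    arr <- array(0, dim = c(length(idx), L, cfg$feature_dim))
    for (i in seq_along(idx)) {
      arr[i, , ] <- x[(ends[idx[i]] - L + 1):ends[idx[i]], ]
    }
    p <- predict_windows(classifier, arr)
    for (i in seq_along(idx)) probs_list[[idx[i]]] <- p[i, , ]
  }

  acc <- accumulator(L, cfg$num_classes)
  results <- list()
  consumed <- -1L
  for (i in seq_len(n_win)) {
    acc <- acc_update(acc, probs_list[[i]], t = ends[i])
    det <- detect_motion(acc, model, horizon = horizon, mode = mode,
                         min_ratio = min_ratio, after = consumed)
    if (det$detected) {
      lo <- max(consumed + 1L, min(det$boundary_frames) - as.integer(margin))
      hi <- ends[i] - 1L
      seg <- segment_motion(acc, model, search_range = c(lo, hi))
      seg$detection_time <- det$detection_time
      seg$score <- det$score
      results[[length(results) + 1]] <- seg
      consumed <- max(seg$boundaries$frame)
    }
  }
  results
}

#' Evaluate detections and boundary localization against ground truth
#'
#' Detection rate is the fraction of recordings with at least one detected
#' motion; boundary errors are absolute frame differences, averaged per
#' boundary state over *detected* recordings only.
#'
#' @param est Tibble of estimated boundaries with columns `recording`,
#'   `label`, `frame` (e.g. row-bound [tidy()] outputs of the first
#'   [run_stream()] result per recording). Undetected recordings are simply
#'   absent.
#' @param truth Tibble of ground-truth boundaries, same columns, covering all
#'   recordings.
#' @return A `segmentation_evaluation` object: list with `per_boundary`
#'   (tibble: `label`, `mean_abs_error`, `n`), `detection_rate`, `n_detected`,
#'   `n_total`.
#' @export
evaluate_segmentation <- function(est, truth) {
  est <- tibble::as_tibble(est)
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("recording", "label", "frame") %in% names(est)),
            all(c("recording", "label", "frame") %in% names(truth)))
  extra <- setdiff(unique(est$recording), unique(truth$recording))
  if (length(extra) > 0) {
    abort(paste0("estimates reference recording(s) absent from truth: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  n_total <- length(unique(truth$recording))
  detected_ids <- unique(est$recording)
  n_detected <- length(detected_ids)

  joined <- dplyr::inner_join(
    est, truth, by = c("recording", "label"), suffix = c("_est", "_true")
  )
  per_boundary <- joined |>
    dplyr::mutate(abs_error = abs(.data$frame_est - .data$frame_true)) |>
    dplyr::group_by(label = .data$label) |>
    dplyr::summarise(mean_abs_error = mean(.data$abs_error),
                     n = dplyr::n(), .groups = "drop")
  # keep the model's temporal ordering if truth supplies it
  per_boundary <- per_boundary[order(match(per_boundary$label,
                                           unique(truth$label))), ]
  structure(list(per_boundary = per_boundary,
                 detection_rate = if (n_total > 0) n_detected / n_total else NA_real_,
                 n_detected = n_detected, n_total = n_total),
            class = "segmentation_evaluation")
}

#' @export
print.segmentation_evaluation <- function(x, ...) {
  cat("<segmentation_evaluation>\n")
  cat(sprintf("  detection rate: %d/%d = %.3f\n", x$n_detected, x$n_total,
              x$detection_rate))
  cat("  per-boundary mean absolute segmentation error (frames):\n")
  print(x$per_boundary)
  invisible(x)
}

#' @export
tidy.segmentation_evaluation <- function(x, ...) x$per_boundary

#' @export
glance.segmentation_evaluation <- function(x, ...) {
  tibble::tibble(
    detection_rate = x$detection_rate,
    n_detected = x$n_detected,
    n_total = x$n_total,
    mean_abs_error = sum(x$per_boundary$mean_abs_error * x$per_boundary$n) /
      sum(x$per_boundary$n)
  )
}

#' @export
autoplot.segmentation_evaluation <- function(object, ...) {
  d <- object$per_boundary
  d$label <- factor(d$label, levels = d$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$mean_abs_error)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "boundary state", y = "mean absolute error (frames)",
                  title = sprintf("Segmentation errors (detection rate %.2f)",
                                  object$detection_rate)) +
    ggplot2::theme_minimal()
}
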