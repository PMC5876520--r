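# Independent straight-loop reference implementations used to cross-check the
# package's vectorized / compiled paths, plus small shared fixtures. These are
# deliberately naive: plain loops, recursion, exhaustive enumeration.

# -- feature formulas, one sample at a time -----------------------------------
oracle_features <- function(stream) {
  a <- as.matrix(stream[, c("ax", "ay", "az")])
  w <- as.matrix(stream[, c("gx", "gy", "gz")])
  t_len <- nrow(a)
  ang <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu < 1e-8 || nv < 1e-8) return(0)
    acos(min(1, max(-1, sum(u * v) / (nu * nv))))
  }
  out <- matrix(0, t_len, 11)
  for (t in seq_len(t_len)) {
    da <- if (t >= 2) a[t, ] - a[t - 1, ] else c(0, 0, 0)
    dw <- if (t >= 2) w[t, ] - w[t - 1, ] else c(0, 0, 0)
    da_prev <- if (t >= 3) a[t - 1, ] - a[t - 2, ] else c(0, 0, 0)
    dw_prev <- if (t >= 3) w[t - 1, ] - w[t - 2, ] else c(0, 0, 0)
    d2a <- da - da_prev
    d2w <- dw - dw_prev
    out[t, 1] <- a[t, 3]
    out[t, 2] <- sqrt(sum(a[t, ]^2))
    out[t, 3] <- sqrt(sum(w[t, ]^2))
    out[t, 4] <- sqrt(sum(da^2))
    out[t, 5] <- sqrt(sum(dw^2))
    out[t, 6] <- sqrt(sum(d2a^2))
    out[t, 7] <- sqrt(sum(d2w^2))
    out[t, 8] <- if (t >= 2) ang(a[t, ], a[t - 1, ]) else 0
    out[t, 9] <- if (t >= 2) ang(w[t, ], w[t - 1, ]) else 0
    out[t, 10] <- if (t >= 2) ang(da, da_prev) else 0
    out[t, 11] <- if (t >= 2) ang(dw, dw_prev) else 0
  }
  out
}

# -- weighted categorical cross-entropy, elementwise --------------------------
oracle_wcce <- function(y_true, y_pred, alpha) {
  total <- 0
  for (i in seq_len(nrow(y_true))) {
    s <- 0
    for (k in seq_len(ncol(y_true))) {
      s <- s - alpha[k] * y_true[i, k] * log(max(y_pred[i, k], 1e-12))
    }
    total <- total + s
  }
  total / nrow(y_true)
}

# -- longest common subsequence, plain recursion ------------------------------
oracle_lcss <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0L)
  if (a[1] == b[1]) return(1L + oracle_lcss(a[-1], b[-1]))
  max(oracle_lcss(a[-1], b), oracle_lcss(a, b[-1]))
}

# -- boundary localization by exhaustive search -------------------------------
# All strictly increasing frame tuples; first maximum found in lexicographic
# enumeration order, i.e. the lexicographically smallest optimum.
oracle_segment <- function(probs, boundary_classes) {
  m <- length(boundary_classes)
  n <- nrow(probs)
  lp <- log(pmax(probs[, boundary_classes + 1, drop = FALSE], 1e-12))
  tuples <- utils::combn(n, m)
  best <- -Inf
  best_tuple <- NULL
  for (j in seq_len(ncol(tuples))) {
    tb <- tuples[, j]
    s <- sum(lp[cbind(tb, seq_len(m))])
    if (s > best) {
      best <- s
      best_tuple <- tb
    }
  }
  list(frames = best_tuple - 1L, score = best)
}

# -- shared fixtures ----------------------------------------------------------
tiny_model <- function(n = 1) {
  phases <- tibble::tibble(
    phase = paste0("phase", seq_len(n)),
    start = paste0("B", seq_len(n)),
    performing = paste0("P", seq_len(n)),
    end = paste0("B", seq_len(n) + 1)
  )
  motion_model(phases, name = paste0("tiny", n))
}

kick_model <- function() {
  read_motion_model(system.file("extdata", "soccer_kick.yaml",
                                package = "motionseg"))
}

throw_model <- function() {
  read_motion_model(system.file("extdata", "two_hand_throw.yaml",
                                package = "motionseg"))
}

random_stream <- function(t_len, seed) {
  set.seed(seed)
  tibble::tibble(
    frame = seq_len(t_len) - 1L,
    ax = rnorm(t_len), ay = rnorm(t_len), az = rnorm(t_len) + 1,
    gx = rnorm(t_len, sd = 100), gy = rnorm(t_len, sd = 100),
    gz = rnorm(t_len, sd = 100)
  )
}

# accumulator prefilled from a bare probability matrix
acc_from_probs <- function(probs, window_len = nrow(probs)) {
  acc <- accumulator(window_len, ncol(probs))
  acc$probs <- probs
  acc$t <- nrow(probs)
  acc
}

# a small trained classifier on a 2-phase synthetic task, cached per session
tiny_trained <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    model <- tiny_model(2)
    spec <- synthetic_spec(model, phase_duration_range = c(8L, 25L),
                           context_range = c(25L, 60L))
    corpus <- generate_corpus(spec, 12, train_fraction = 0.75, seed = 99)
    cfg <- classifier_config(
      num_classes = n_classes(model), window_len = 40L, dense_units = 24L,
      gru_units = c(16L, 12L), epochs = 15L, batch_size = 50L, seed = 99L
    )
    cl <- fit_motion_classifier(corpus$train, model, config = cfg, stride = 3L)
    cache <<- list(model = model, spec = spec, corpus = corpus,
                   classifier = cl)
    cache
  }
})
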