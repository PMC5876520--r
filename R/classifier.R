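#' Configuration of the per-timestep sequence classifier
#'
#' The network labels every frame of a fixed-length window of feature vectors
#' with a state-probability vector. Architecture: a time-distributed dense
#' layer (48 units, batch norm, ELU) feeding two stacked bidirectional GRU
#' layers (cell sizes 48 and 32, outputs concatenated so 96 and 64 wide, batch
#' norm on their outputs), then a per-timestep softmax over the `K` classes of
#' the motion model. Dropout is applied to every hidden layer, never to the
#' output. Training uses Adam on class-weighted categorical cross-entropy.
#'
#' @param num_classes Number of classes `K` (for a model with `N` phases,
#'   `2N + 2` including the none class) — see [n_classes()].
#' @param window_len Window length `L` in frames (default 100, i.e. 1 s at
#'   100 Hz).
#' @param feature_dim Number of features per frame (11).
#' @param dense_units Width of the first dense layer.
#' @param gru_units Cell sizes of the two bidirectional GRU layers.
#' @param dropout_rate Dropout fraction on hidden layers, in `[0, 1)`.
#' @param batch_size Mini-batch size (windows per gradient step).
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(num_classes, window_len = 100L, feature_dim = 11L,
                              dense_units = 48L, gru_units = c(48L, 32L),
                              dropout_rate = 0.2, batch_size = 100L,
                              epochs = 20L, learning_rate = 1e-3, seed = 1L) {
  stopifnot(num_classes >= 4, window_len >= 1, feature_dim >= 1,
            length(gru_units) == 2, all(gru_units >= 1),
            dropout_rate >= 0, dropout_rate < 1,
            batch_size >= 1, epochs >= 0, learning_rate > 0)
  structure(list(
    num_classes = as.integer(num_classes), window_len = as.integer(window_len),
    feature_dim = as.integer(feature_dim), dense_units = as.integer(dense_units),
    gru_units = as.integer(gru_units), dropout_rate = dropout_rate,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    learning_rate = learning_rate, seed = as.integer(seed)
  ), class = "classifier_config")
}

#' Slice a labeled feature sequence into fixed-length training windows
#'
#' Sliding-window dataset construction: windows start at offsets
#' `0, stride, 2 * stride, ...` up to `T - L`, giving
#' `floor((T - L) / stride) + 1` windows, each paired with its per-frame
#' labels. Dense striding (`stride = 1`) extracts the maximal number of
#' training sequences from each recording.
#'
#' @param features Feature tibble ([extract_features()]), `T >= window_len`
#'   rows.
#' @param labels Integer vector of per-frame class indices, length `T`.
#' @param window_len Window length `L` in frames.
#' @param stride Offset between consecutive windows, `>= 1`.
#' @return A `window_set`: list with `inputs` (`M x L x 11` array), `targets`
#'   (`M x L` integer matrix), and `offsets` (0-based window starts).
#' @export
make_windows <- function(features, labels, window_len = 100L, stride = 1L) {
  x <- as.matrix(features[, feature_cols])
  t_len <- nrow(x)
  stopifnot(length(labels) == t_len, stride >= 1, window_len >= 1)
  if (t_len < window_len) {
    abort(paste0("sequence of length ", t_len,
                 " is shorter than the window length ", window_len))
  }
  offsets <- seq(0L, t_len - window_len, by = as.integer(stride))
  m <- length(offsets)
  inputs <- array(0, dim = c(m, window_len, ncol(x)))
  targets <- matrix(0L, m, window_len)
  for (i in seq_len(m)) {
    rows <- (offsets[i] + 1):(offsets[i] + window_len)
    inputs[i, , ] <- x[rows, ]
    targets[i, ] <- as.integer(labels[rows])
  }
  structure(list(inputs = inputs, targets = targets, offsets = offsets),
            class = "window_set")
}

#' Combine window sets from several recordings into one training set
#' @param sets A list of `window_set` objects with identical `L` and feature
#'   dimension.
#' @return A single `window_set` (offsets dropped).
#' @export
combine_window_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  dims <- dim(sets[[1]]$inputs)
  m_total <- sum(vapply(sets, function(s) dim(s$inputs)[1], integer(1)))
  inputs <- array(0, dim = c(m_total, dims[2], dims[3]))
  targets <- matrix(0L, m_total, dims[2])
  at <- 0L
  for (s in sets) {
    m <- dim(s$inputs)[1]
    inputs[at + seq_len(m), , ] <- s$inputs
    targets[at + seq_len(m), ] <- s$targets
    at <- at + m
  }
  structure(list(inputs = inputs, targets = targets, offsets = NULL),
            class = "window_set")
}

#' Per-class totals of a window set's targets
#' @param windows A `window_set`.
#' @param num_classes `K`.
#' @return Integer vector of length `K` (counts for classes `0..K-1`).
#' @export
window_class_counts <- function(windows, num_classes) {
  tabulate(as.vector(windows$targets) + 1L, nbins = num_classes)
}

#' Inverse-frequency class weights for the imbalance-weighted loss
#'
#' Boundary states occupy a single frame per performance, so their labels are
#' orders of magnitude rarer than performing or none labels; unweighted
#' cross-entropy would happily ignore them. The weight of class `i` is
#' `total / (K * count_i)` — inversely proportional to the class's total count
#' and normalized so that balanced counts give weight 1 everywhere. Classes
#' with zero count get weight 0.
#'
#' @param class_counts Non-negative per-class totals (length `K`).
#' @return Numeric weight vector of length `K`.
#' @examples
#' class_weights(c(50, 50))  # 1, 1
#' class_weights(c(90, 10))  # 5/9, 5
#' @export
class_weights <- function(class_counts) {
  stopifnot(all(class_counts >= 0))
  if (all(class_counts == 0)) abort("all class counts are zero")
  k <- length(class_counts)
  total <- sum(class_counts)
  w <- ifelse(class_counts > 0, total / (k * class_counts), 0)
  as.numeric(w)
}

#' Class-weighted categorical cross-entropy
#'
#' Mean over samples of `-sum_i alpha_i * y_i * log(yhat_i)`, the training
#' loss of the sequence classifier. Predicted probabilities are clamped at a
#' small floor before the log for numerical safety. With all weights 1 this is
#' standard categorical cross-entropy.
#'
#' @param y_true One-hot matrix (`n x K`).
#' @param y_pred Probability matrix (`n x K`), rows summing to 1.
#' @param alpha Per-class weights, length `K` (default all 1).
#' @param floor Clamp for the log argument.
#' @return Non-negative scalar loss.
#' @export
weighted_cce <- function(y_true, y_pred, alpha = rep(1, ncol(y_true)),
                         floor = 1e-12) {
  stopifnot(identical(dim(y_true), dim(y_pred)),
            length(alpha) == ncol(y_true))
  lp <- log(pmax(y_pred, floor))
  mean(-rowSums(sweep(y_true * lp, 2, alpha, `*`)))
}

#' One-hot encode integer class labels
#' @param labels Integer vector of 0-based class indices.
#' @param num_classes `K`.
#' @return `length(labels) x K` binary matrix.
#' @export
one_hot <- function(labels, num_classes) {
  stopifnot(all(labels >= 0), all(labels < num_classes))
  out <- matrix(0, length(labels), num_classes)
  out[cbind(seq_along(labels), labels + 1L)] <- 1
  out
}

# ---- network construction and training -------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_params <- function(cfg) {
  d <- cfg$feature_dim; h1 <- cfg$dense_units
  u1 <- cfg$gru_units[1]; u2 <- cfg$gru_units[2]; k <- cfg$num_classes
  gru_par <- function(n_in, u) {
    list(Wx = glorot(n_in, 3 * u), Uh = glorot(u, 3 * u), b = numeric(3 * u))
  }
  g1f <- gru_par(h1, u1); g1b <- gru_par(h1, u1)
  g2f <- gru_par(2 * u1, u2); g2b <- gru_par(2 * u1, u2)
  list(
    W1 = glorot(d, h1), bn1_gamma = rep(1, h1), bn1_beta = numeric(h1),
    gru1f_Wx = g1f$Wx, gru1f_Uh = g1f$Uh, gru1f_b = g1f$b,
    gru1b_Wx = g1b$Wx, gru1b_Uh = g1b$Uh, gru1b_b = g1b$b,
    bn2_gamma = rep(1, 2 * u1), bn2_beta = numeric(2 * u1),
    gru2f_Wx = g2f$Wx, gru2f_Uh = g2f$Uh, gru2f_b = g2f$b,
    gru2b_Wx = g2b$Wx, gru2b_Uh = g2b$Uh, gru2b_b = g2b$b,
    bn3_gamma = rep(1, 2 * u2), bn3_beta = numeric(2 * u2),
    Wo = glorot(2 * u2, k), bo = numeric(k)
  )
}

init_running <- function(cfg) {
  h1 <- cfg$dense_units; u1 <- cfg$gru_units[1]; u2 <- cfg$gru_units[2]
  list(bn1_mean = numeric(h1), bn1_var = rep(1, h1),
       bn2_mean = numeric(2 * u1), bn2_var = rep(1, 2 * u1),
       bn3_mean = numeric(2 * u2), bn3_var = rep(1, 2 * u2))
}

#' Build an (untrained) sequence classifier
#'
#' Initializes the network of [classifier_config()] with Glorot-uniform
#' weights drawn under the config's seed. The parameter count depends only on
#' layer widths and `K`, never on the window length (recurrent weights are
#' shared across time).
#'
#' @param config A [classifier_config()].
#' @return A `seq_classifier` object.
#' @export
seq_classifier <- function(config) {
  stopifnot(inherits(config, "classifier_config"))
  old <- .Random.seed_exists()
  set.seed(config$seed)
  params <- init_params(config)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(
    config = config, params = params, running = init_running(config),
    feature_stats = NULL, alpha = rep(1, config$num_classes),
    trained = FALSE, history = NULL
  ), class = "seq_classifier")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

#' @export
print.seq_classifier <- function(x, ...) {
  cfg <- x$config
  cat("<seq_classifier> ", if (x$trained) "trained" else "untrained", "\n",
      sep = "")
  cat(sprintf(
    "  dense(%d, ELU) -> biGRU(%d) -> biGRU(%d) -> softmax(%d), L = %d\n",
    cfg$dense_units, cfg$gru_units[1], cfg$gru_units[2], cfg$num_classes,
    cfg$window_len))
  cat("  parameters:", n_params(x), "\n")
  if (!is.null(x$history)) {
    cat("  final training loss:",
        format(tail(x$history$loss, 1), digits = 4), "\n")
  }
  invisible(x)
}

#' Number of trainable parameters of a classifier
#' @param classifier A `seq_classifier`.
#' @return Integer.
#' @export
n_params <- function(classifier) {
  sum(vapply(classifier$params, length, integer(1)))
}

#' Train the sequence classifier on a window set
#'
#' Mini-batch Adam on the class-weighted categorical cross-entropy, with
#' per-epoch reshuffling. Class weights default to [class_weights()] of the
#' window set's label totals. All randomness (shuffling, dropout) derives from
#' the config seed, so a fixed seed reproduces the run exactly.
#'
#' @param classifier A `seq_classifier`.
#' @param windows A `window_set` from [make_windows()] /
#'   [combine_window_sets()].
#' @param alpha Per-class loss weights; `NULL` computes inverse-frequency
#'   weights from the window set.
#' @param epochs Override the config's epoch count.
#' @param verbose Print per-epoch loss.
#' @return The trained classifier, with a `history` tibble
#'   (`epoch`, `loss`) attached.
#' @export
train_classifier <- function(classifier, windows, alpha = NULL, epochs = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(classifier, "seq_classifier"),
            inherits(windows, "window_set"))
  cfg <- classifier$config
  m <- dim(windows$inputs)[1]
  if (m == 0) abort("empty window set")
  if (dim(windows$inputs)[2] != cfg$window_len) {
    abort("window set length does not match the classifier's window_len")
  }
  epochs <- epochs %||% cfg$epochs
  counts <- window_class_counts(windows, cfg$num_classes)
  if (is.null(alpha)) alpha <- class_weights(counts)
  stopifnot(length(alpha) == cfg$num_classes)

  params <- classifier$params
  running <- classifier$running
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- numeric(epochs)

  set.seed(cfg$seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(m)
    batch_starts <- seq(1L, m, by = cfg$batch_size)
    ep_loss <- 0; ep_n <- 0
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + cfg$batch_size - 1L, m)]
      # cube layout expected by the compiled core: (batch, feature, time)
      xb <- aperm(windows$inputs[idx, , , drop = FALSE], c(1, 3, 2))
      yb <- windows$targets[idx, , drop = FALSE]
      batch_seed <- sample.int(.Machine$integer.max, 1L)
      out <- cpp_net_train_batch(params, running, xb, yb, alpha,
                                 cfg$dropout_rate, 0.99, batch_seed, TRUE)
      running <- out$running
      step <- step + 1L
      lr_t <- cfg$learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
      g <- out$grads
      for (nm in names(params)) {
        gi <- g[[nm]]
        if (is.null(dim(params[[nm]]))) gi <- as.numeric(gi)
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gi
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gi^2
        params[[nm]] <- params[[nm]] -
          lr_t * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
      }
      if (!is.finite(out$loss)) {
        abort(paste0("training diverged: non-finite loss at epoch ", ep,
                     " (lower the learning rate or check the inputs)"))
      }
      ep_loss <- ep_loss + out$loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    history[ep] <- ep_loss / ep_n
    if (verbose) {
      message(sprintf("epoch %d/%d: weighted loss %.4f", ep, epochs,
                      history[ep]))
    }
  }

  classifier$params <- params
  classifier$running <- running
  classifier$alpha <- alpha
  classifier$trained <- epochs > 0
  classifier$history <- tibble::tibble(epoch = seq_len(epochs), loss = history)
  classifier
}

#' Per-timestep state probabilities for one window
#'
#' Runs the classifier in inference mode (dropout off, batch norm on running
#' statistics); deterministic for a fixed trained network.
#'
#' @param classifier A `seq_classifier`.
#' @param x An `L x 11` matrix of (standardized) feature vectors.
#' @return `L x K` matrix of state probabilities, rows summing to 1.
#' @export
predict_window <- function(classifier, x) {
  x <- as.matrix(x)
  cfg <- classifier$config
  if (nrow(x) != cfg$window_len || ncol(x) != cfg$feature_dim) {
    abort(paste0("expected a ", cfg$window_len, " x ", cfg$feature_dim,
                 " window, got ", nrow(x), " x ", ncol(x)))
  }
  predict_windows(classifier, array(x, dim = c(1, nrow(x), ncol(x))))[1, , ]
}

#' Per-timestep state probabilities for a batch of windows
#' @param classifier A `seq_classifier`.
#' @param inputs `M x L x 11` array.
#' @return `M x L x K` array of probabilities.
#' @export
predict_windows <- function(classifier, inputs) {
  stopifnot(length(dim(inputs)) == 3)
  cfg <- classifier$config
  xb <- aperm(inputs, c(1, 3, 2))
  probs <- cpp_net_forward(classifier$params, classifier$running, xb)
  aperm(probs, c(1, 3, 2))
}

#' Training loss on a window set without updating the network
#'
#' Evaluates the class-weighted cross-entropy in training mode (batch
#' statistics, dropout disabled via rate 0, running stats untouched).
#' @param classifier A `seq_classifier`.
#' @param windows A `window_set`.
#' @param alpha Per-class weights (default: the classifier's stored weights).
#' @return Scalar loss.
#' @export
evaluate_loss <- function(classifier, windows, alpha = NULL) {
  cfg <- classifier$config
  alpha <- alpha %||% classifier$alpha
  xb <- aperm(windows$inputs, c(1, 3, 2))
  out <- cpp_net_train_batch(classifier$params, classifier$running, xb,
                             windows$targets, alpha, 0, 0.99, 1L, FALSE)
  out$loss
}

# ---- persistence -----------------------------------------------------------

#' Save / load a classifier checkpoint
#'
#' The checkpoint is a single JSON file holding the config, the feature
#' standardization statistics, the class weights, all network parameters and
#' the batch-norm running statistics — plain text, no binary formats.
#'
#' @param classifier A `seq_classifier`.
#' @param path Checkpoint path (`.json`).
#' @return `save_classifier()` returns `path` invisibly; `load_classifier()`
#'   returns the restored `seq_classifier`.
#' @export
save_classifier <- function(classifier, path) {
  obj <- list(
    config = unclass(classifier$config),
    params = lapply(classifier$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    running = classifier$running,
    feature_stats = classifier$feature_stats,
    alpha = classifier$alpha,
    trained = classifier$trained,
    history = classifier$history
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(classifier_config, obj$config[c(
    "num_classes", "window_len", "feature_dim", "dense_units", "gru_units",
    "dropout_rate", "batch_size", "epochs", "learning_rate", "seed")])
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else as.numeric(p$data)
  })
  cl <- structure(list(
    config = cfg, params = params,
    running = lapply(obj$running, as.numeric),
    feature_stats = if (is.null(obj$feature_stats)) NULL
                    else tibble::as_tibble(obj$feature_stats),
    alpha = as.numeric(obj$alpha),
    trained = isTRUE(obj$trained),
    history = if (is.null(obj$history)) NULL else tibble::as_tibble(obj$history)
  ), class = "seq_classifier")
  cl
}

# ---- broom-style methods ---------------------------------------------------

#' @export
tidy.seq_classifier <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), loss = numeric()))
  }
  x$history
}

#' @export
glance.seq_classifier <- function(x, ...) {
  tibble::tibble(
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else tail(x$history$loss, 1),
    n_params = n_params(x),
    num_classes = x$config$num_classes,
    window_len = x$config$window_len
  )
}

#' @export
autoplot.seq_classifier <- function(object, ...) {
  h <- tidy(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy",
                  title = "Training history") +
    ggplot2::theme_minimal()
}
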