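#' Default per-state signal signatures for a motion model
#'
#' Every state of the model (plus the none state) gets a signal signature: a
#' base acceleration 3-vector (g, earth frame, gravity included), a base
#' angular-velocity 3-vector (deg/s), an oscillation frequency (Hz) and
#' amplitude. Performing states get well-separated bases laid out
#' deterministically around the unit sphere with staggered magnitudes and
#' distinct oscillation frequencies, so the per-frame feature vectors carry
#' enough information to tell states apart. Boundary states get the *mean* of
#' their two neighboring signatures (the none state counting as neighbor at
#' the motion's ends), which makes boundary frames genuinely transitional —
#' the hardest case for single-frame localization. The none state is a quiet
#' stance/walking signature: gravity plus low-frequency sway.
#'
#' @param model A [motion_model()].
#' @return Tibble with one row per class (`class_index` 0..2N+1): `label`,
#'   `ax, ay, az, gx, gy, gz` (bases), `freq`, `amp`.
#' @export
default_signatures <- function(model) {
  n <- model$n_phases
  none <- c(0, 0, 1, 0, 0, 0)
  perf <- matrix(0, n, 6)
  freq <- numeric(n)
  amp <- numeric(n)
  for (i in seq_len(n)) {
    th <- 2 * pi * (i - 1) / n + 0.7
    r <- 1.2 + 0.5 * ((i - 1) %% 3)
    dir <- c(cos(th), sin(th), 0.35 * (-1)^i)
    accel <- c(0, 0, 1) + r * dir / sqrt(sum(dir^2))
    th2 <- 2 * pi * (i - 1) / n + 2.1
    gmag <- 180 + 120 * ((i + 1) %% 3)
    gdir <- c(sin(th2), cos(th2), 0.5 * (-1)^i)
    gyro <- gmag * gdir / sqrt(sum(gdir^2))
    perf[i, ] <- c(accel, gyro)
    freq[i] <- 2 + 1.3 * i
    amp[i] <- 0.45 + 0.12 * i
  }
  # temporal order: b1, p1, b2, p2, ..., b_{N+1}
  rows <- vector("list", 2 * n + 1)
  for (k in seq_len(n + 1)) { # boundary k sits between phases k-1 and k
    prev <- if (k == 1) none else perf[k - 1, ]
    nxt <- if (k == n + 1) none else perf[k, ]
    pf <- mean(c(if (k == 1) 1.6 else freq[k - 1],
                 if (k == n + 1) 1.6 else freq[k]))
    pa <- mean(c(if (k == 1) 0.3 else amp[k - 1],
                 if (k == n + 1) 0.3 else amp[k]))
    rows[[2 * k - 1]] <- c((prev + nxt) / 2, pf, pa)
  }
  for (i in seq_len(n)) rows[[2 * i]] <- c(perf[i, ], freq[i], amp[i])
  sig <- do.call(rbind, c(list(c(none, 1.6, 0.3)), rows))
  out <- tibble::as_tibble(as.data.frame(sig))
  names(out) <- c("ax", "ay", "az", "gx", "gy", "gz", "freq", "amp")
  out$class_index <- 0:(2 * n + 1)
  out$label <- c("none", model$states$label)
  out[, c("label", "class_index", "ax", "ay", "az", "gx", "gy", "gz",
          "freq", "amp")]
}

#' Specification of the synthetic IMU recording generator
#'
#' Emulates the structure of wearable-sensor sports recordings: roughly five
#' seconds at 100 Hz containing one performance of the modeled motion embedded
#' in irrelevant movement (walking-like clutter) on both sides. Performing
#' states last a random number of frames, boundary states exactly one frame.
#'
#' @param model A [motion_model()].
#' @param phase_duration_range Min/max frames per performing state (default
#'   10–80, i.e. 0.1–0.8 s).
#' @param context_range Min/max frames of none-state context before and after
#'   the motion (default 50–150).
#' @param signatures Per-state signatures; default [default_signatures()].
#' @param noise_sd Per-channel Gaussian noise sd, length 6
#'   (`ax, ay, az` in g, `gx, gy, gz` in deg/s).
#' @param sample_rate Hz.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(model, phase_duration_range = c(10L, 80L),
                           context_range = c(50L, 150L),
                           signatures = default_signatures(model),
                           noise_sd = c(0.08, 0.08, 0.08, 12, 12, 12),
                           sample_rate = 100) {
  stopifnot(inherits(model, "motion_model"),
            phase_duration_range[1] >= 2, # performing states need >= 2 frames
            diff(phase_duration_range) >= 0,
            context_range[1] >= 0, diff(context_range) >= 0,
            length(noise_sd) == 6, all(noise_sd >= 0),
            nrow(signatures) == 2 * model$n_phases + 2)
  structure(list(
    model = model,
    phase_duration_range = as.integer(phase_duration_range),
    context_range = as.integer(context_range),
    signatures = signatures, noise_sd = noise_sd, sample_rate = sample_rate
  ), class = "synthetic_spec")
}

ACCEL_RANGE_G <- 16
GYRO_RANGE_DPS <- 2000

#' Generate one synthetic labeled IMU recording
#'
#' Draws per-phase durations and context lengths, lays out the label sequence
#' (none ... b1, p1, b2, ..., b_{N+1} ... none, boundaries single-frame),
#' then synthesizes each channel as the state's base value plus sinusoidal
#' modulation at the state's frequency/amplitude (random phase offsets per
#' recording) plus white Gaussian noise. Values are clipped to the sensor
#' ranges (±16 g, ±2000 deg/s) with a warning if clipping occurs. The same
#' seed reproduces the recording exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List with `stream` (tibble `frame, ax..gz`), `labels` (integer
#'   class index per frame), `boundaries` (tibble `label`, `frame`: the
#'   ground-truth boundary frames, 0-based).
#' @export
generate_recording <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- spec$model
  n <- model$n_phases
  old <- .Random.seed_exists()
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  durs <- sample(spec$phase_duration_range[1]:spec$phase_duration_range[2], n,
                 replace = TRUE)
  pre <- sample(spec$context_range[1]:spec$context_range[2], 1)
  post <- sample(spec$context_range[1]:spec$context_range[2], 1)

  labels <- c(rep(0L, pre))
  for (i in seq_len(n)) {
    labels <- c(labels, 2L * i - 1L, rep(2L * i, durs[i])) # b_i then p_i
  }
  labels <- c(labels, 2L * n + 1L, rep(0L, post)) # final boundary, post context
  t_len <- length(labels)

  sig <- spec$signatures
  base <- as.matrix(sig[match(labels, sig$class_index),
                        c("ax", "ay", "az", "gx", "gy", "gz")])
  freq <- sig$freq[match(labels, sig$class_index)]
  amp <- sig$amp[match(labels, sig$class_index)]

  phases6 <- runif(6, 0, 2 * pi)
  # oscillation depth per channel: amp g on accel, amp * 60 deg/s on gyro
  osc_scale <- c(1, 0.8, 0.6, 60, 54, 42)
  tt <- (seq_len(t_len) - 1) / spec$sample_rate
  osc <- sin(outer(2 * pi * freq * tt, rep(1, 6)) +
             matrix(phases6, t_len, 6, byrow = TRUE))
  signal <- base + osc * outer(amp, osc_scale)
  noise <- matrix(rnorm(t_len * 6), t_len, 6) %*% diag(spec$noise_sd)
  signal <- signal + noise

  lim <- rep(c(ACCEL_RANGE_G, GYRO_RANGE_DPS), c(3, 3))
  clipped <- sweep(abs(signal), 2, lim, `>`)
  if (any(clipped)) {
    warn(paste0("clipping ", sum(clipped), " sample value(s) to sensor range"))
    signal <- pmin(pmax(signal, matrix(-lim, t_len, 6, byrow = TRUE)),
                   matrix(lim, t_len, 6, byrow = TRUE))
  }

  stream <- tibble::tibble(
    frame = seq_len(t_len) - 1L,
    ax = signal[, 1], ay = signal[, 2], az = signal[, 3],
    gx = signal[, 4], gy = signal[, 5], gz = signal[, 6]
  )
  bnd_classes <- boundary_states(model)
  boundaries <- tibble::tibble(
    label = model$states$label[model$states$role == "boundary"],
    frame = vapply(bnd_classes, function(k) which(labels == k)[1] - 1L,
                   integer(1))
  )
  list(stream = stream, labels = labels, boundaries = boundaries)
}

#' Generate a train/test corpus of synthetic recordings
#'
#' Durations, context lengths, oscillation phases and noise are resampled per
#' recording (each recording gets its own derived seed), and the train/test
#' split is done per *recording* — never per window — mirroring how motion
#' recordings are split in practice.
#'
#' @param spec A [synthetic_spec()].
#' @param n_recordings Number of recordings, `>= 2`.
#' @param train_fraction Fraction assigned to the training split.
#' @param seed Integer master seed.
#' @return List with `train` and `test` (lists of recordings as returned by
#'   [generate_recording()], each with an `id` added) and `manifest` (tibble
#'   `id`, `seed`, `split`).
#' @export
generate_corpus <- function(spec, n_recordings, train_fraction = 0.8,
                            seed = 1L) {
  stopifnot(n_recordings >= 2)
  n_train <- round(n_recordings * train_fraction)
  if (n_train < 1 || n_train >= n_recordings) {
    abort("degenerate split: need at least one training and one test recording")
  }
  old <- .Random.seed_exists()
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  rec_seeds <- sample.int(2^31 - 2, n_recordings)
  train_idx <- sort(sample.int(n_recordings, n_train))

  make_rec <- function(i) {
    rec <- generate_recording(spec, seed = rec_seeds[i])
    rec$id <- sprintf("rec%04d", i)
    rec
  }
  train <- lapply(train_idx, make_rec)
  test <- lapply(setdiff(seq_len(n_recordings), train_idx), make_rec)
  manifest <- tibble::tibble(
    id = sprintf("rec%04d", seq_len(n_recordings)),
    seed = rec_seeds,
    split = ifelse(seq_len(n_recordings) %in% train_idx, "train", "test")
  )
  list(train = train, test = test, manifest = manifest)
}

#' Nearest-signature frame classifier (feasibility diagnostic)
#'
#' Assigns every frame to the state whose base signature is nearest in a
#' normalized channel space (gyro divided by 100 so both sensor types weigh
#' comparably). This deliberately ignorant classifier bounds the difficulty of
#' the synthetic task: if it already recovers most frame labels, the learning
#' problem posed to the sequence classifier is feasible.
#'
#' @param stream IMU stream data frame.
#' @param spec The [synthetic_spec()] that generated it.
#' @return Integer vector of class indices per frame.
#' @export
nearest_signature_labels <- function(stream, spec) {
  scale6 <- rep(c(1, 1 / 100), c(3, 3))
  x <- as.matrix(stream[, imu_channel_cols]) %*% diag(scale6)
  s <- as.matrix(spec$signatures[, imu_channel_cols]) %*% diag(scale6)
  d2 <- outer(rowSums(x^2), rep(1, nrow(s))) - 2 * x %*% t(s) +
    outer(rep(1, nrow(x)), rowSums(s^2))
  spec$signatures$class_index[max.col(-d2, ties.method = "first")]
}
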