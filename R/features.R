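#' Feature column names, in fixed order
#'
#' The 11 per-sample features derived from a six-channel IMU stream, in the
#' order every downstream consumer (classifier input, standardization stats)
#' assumes: vertical acceleration `a_z`; magnitudes of acceleration, angular
#' velocity, and their first and second backward differences; and the angles
#' between adjacent acceleration, angular-velocity, and first-difference
#' vectors.
#' @export
feature_cols <- c(
  "a_z", "a_mag", "w_mag", "da_mag", "dw_mag", "d2a_mag", "d2w_mag",
  "a_ang", "w_ang", "da_ang", "dw_ang"
)

imu_channel_cols <- c("ax", "ay", "az", "gx", "gy", "gz")

#' Angle between two 3-vectors
#'
#' `acos` of the clamped normalized dot product. If either vector's magnitude
#' is below `eps` the angle is defined as 0 (degenerate-by-contract): this is
#' what makes the angle features well defined at rest and at the zero-padded
#' first samples of a stream.
#'
#' @param u,v Numeric 3-vectors, or matrices with 3 columns (rowwise angles).
#' @param eps Magnitude threshold below which a vector counts as degenerate.
#' @return Angle(s) in radians, in `[0, pi]`.
#' @examples
#' angle_between(c(1, 0, 0), c(0, 1, 0))  # pi / 2
#' angle_between(c(2, 0, 0), c(1, 0, 0))  # 0
#' angle_between(c(0, 0, 0), c(1, 2, 3))  # 0 by contract
#' @export
angle_between <- function(u, v, eps = 1e-8) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  stopifnot(ncol(u) == 3, ncol(v) == 3, nrow(u) == nrow(v))
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  dot <- rowSums(u * v)
  out <- numeric(nrow(u))
  ok <- nu >= eps & nv >= eps
  cosv <- dot[ok] / (nu[ok] * nv[ok])
  out[ok] <- acos(pmin(1, pmax(-1, cosv)))
  if (length(out) == 1) out[1] else out
}

#' Extract the 11-element per-sample feature vectors from an IMU stream
#'
#' Converts a raw six-channel stream (global-frame acceleration `ax, ay, az`,
#' sensor-frame angular velocity `gx, gy, gz`) into one feature row per sample.
#' Derivatives are backward finite differences of the raw samples
#' (`dv[t] = v[t] - v[t-1]`, `d2v[t] = dv[t] - dv[t-1]`), *not* divided by the
#' sample interval: at a constant rate the interval is a scale factor absorbed
#' by standardization. Rows whose differences are undefined (the first one or
#' two samples) use zero vectors for the missing differences, so the feature
#' sequence stays index-aligned with the raw stream; the angle of a degenerate
#' (near-zero) vector is 0 by the [angle_between()] contract.
#'
#' Gravity is not removed: with the sensor reporting acceleration in the earth
#' frame, the vertical channel `a_z` carries the gravity-relative information
#' the first feature is designed to expose. Set `subtract_gravity = TRUE` to
#' subtract 1 g from `az` first (only meaningful if the stream is in g).
#'
#' @param stream Data frame with columns `ax, ay, az, gx, gy, gz` (a `frame`
#'   column, if present, is carried through; otherwise frames are numbered
#'   from 0).
#' @param subtract_gravity Subtract 1 (g) from `az` before computing features.
#' @param eps Degenerate-vector threshold passed to [angle_between()].
#' @return A tibble with a `frame` column plus the 11 columns of
#'   [feature_cols], one row per input sample.
#' @export
extract_features <- function(stream, subtract_gravity = FALSE, eps = 1e-8) {
  stream <- as.data.frame(stream)
  missing_cols <- setdiff(imu_channel_cols, names(stream))
  if (length(missing_cols) > 0) {
    abort(paste0("stream is missing channel(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  t_len <- nrow(stream)
  if (t_len == 0) abort("stream is empty")
  a <- as.matrix(stream[, c("ax", "ay", "az")])
  w <- as.matrix(stream[, c("gx", "gy", "gz")])
  if (!all(is.finite(a)) || !all(is.finite(w))) {
    abort("stream contains non-finite sensor values")
  }
  if (subtract_gravity) a[, 3] <- a[, 3] - 1

  diff0 <- function(m) rbind(matrix(0, 1, 3), diff(m))  # zero-padded backward diff
  da <- diff0(a); dw <- diff0(w)
  d2a <- diff0(da); d2w <- diff0(dw)

  lagm <- function(m) rbind(matrix(0, 1, 3), m[-nrow(m), , drop = FALSE])
  ang <- function(m) angle_between(m, lagm(m), eps = eps)

  frame <- if ("frame" %in% names(stream)) stream$frame else seq_len(t_len) - 1L
  tibble::tibble(
    frame = frame,
    a_z = a[, 3],
    a_mag = sqrt(rowSums(a^2)),
    w_mag = sqrt(rowSums(w^2)),
    da_mag = sqrt(rowSums(da^2)),
    dw_mag = sqrt(rowSums(dw^2)),
    d2a_mag = sqrt(rowSums(d2a^2)),
    d2w_mag = sqrt(rowSums(d2w^2)),
    a_ang = if (t_len == 1) 0 else ang(a),
    w_ang = if (t_len == 1) 0 else ang(w),
    da_ang = if (t_len == 1) 0 else ang(da),
    dw_ang = if (t_len == 1) 0 else ang(dw)
  )
}

#' Per-column standardization statistics
#'
#' Computes the mean and standard deviation of every feature column, to be
#' fitted on the *training* split only and applied everywhere else. Columns
#' with zero spread get their scale clamped to 1 so standardization maps them
#' to 0 rather than NaN.
#'
#' @param features A feature tibble from [extract_features()], or a row-bound
#'   concatenation of several.
#' @return A tibble with columns `feature`, `mean`, `scale`.
#' @export
feature_stats <- function(features) {
  x <- as.matrix(features[, feature_cols])
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  clamped <- !is.finite(sdv) | sdv < 1e-12
  if (any(clamped)) {
    warn(paste0("constant feature column(s) ",
                paste(feature_cols[clamped], collapse = ", "),
                ": scale clamped to 1"))
    sdv[clamped] <- 1
  }
  tibble::tibble(feature = feature_cols, mean = unname(mu), scale = unname(sdv))
}

#' Standardize (or invert standardization of) a feature sequence
#'
#' `(x - mean) / scale` per column, using statistics from [feature_stats()].
#'
#' @param features A feature tibble.
#' @param stats A stats tibble from [feature_stats()]. `NULL` is the identity
#'   transform (standardization disabled).
#' @param inverse Undo the transform instead.
#' @return A feature tibble of the same shape.
#' @export
standardize_features <- function(features, stats, inverse = FALSE) {
  if (is.null(stats)) return(features)
  stopifnot(identical(stats$feature, feature_cols))
  out <- features
  for (i in seq_along(feature_cols)) {
    col <- feature_cols[i]
    if (inverse) {
      out[[col]] <- features[[col]] * stats$scale[i] + stats$mean[i]
    } else {
      out[[col]] <- (features[[col]] - stats$mean[i]) / stats$scale[i]
    }
  }
  out
}
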