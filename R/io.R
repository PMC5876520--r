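#' Read / write an IMU stream CSV
#'
#' One recording per file: a header row and the columns `frame, ax, ay, az,
#' gx, gy, gz` (acceleration in g, earth frame; angular velocity in deg/s,
#' sensor frame). Lines starting with `#` are treated as metadata comments.
#' Malformed files are rejected with the offending column or line named.
#'
#' @param path File path.
#' @return `read_imu_csv()` returns a stream tibble; `write_imu_csv()` returns
#'   `path` invisibly.
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0) abort(paste0("empty IMU file: ", path))
  missing_cols <- setdiff(c("frame", imu_channel_cols), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0(path, ": malformed value(s) at line(s) ",
                 paste(head(probs$row, 5), collapse = ", ")))
  }
  for (col in c("frame", imu_channel_cols)) {
    if (!is.numeric(df[[col]])) {
      abort(paste0(path, ": column ", col, " is not numeric"))
    }
  }
  df[, c("frame", imu_channel_cols)]
}

#' @rdname read_imu_csv
#' @param stream Stream tibble (`frame, ax..gz`).
#' @export
write_imu_csv <- function(stream, path) {
  stopifnot(all(c("frame", imu_channel_cols) %in% names(stream)))
  readr::write_csv(stream[, c("frame", imu_channel_cols)], path)
  invisible(path)
}

#' Read / write per-frame state labels
#'
#' CSV with columns `frame, state_index` (0 = none).
#' @param path File path.
#' @return `read_labels_csv()` returns an integer vector ordered by frame.
#' @export
read_labels_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing_cols <- setdiff(c("frame", "state_index"), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  as.integer(df$state_index[order(df$frame)])
}

#' @rdname read_labels_csv
#' @param labels Integer vector of per-frame class indices.
#' @export
write_labels_csv <- function(labels, path) {
  readr::write_csv(
    tibble::tibble(frame = seq_along(labels) - 1L,
                   state_index = as.integer(labels)),
    path
  )
  invisible(path)
}

#' Write a corpus of synthetic recordings to a directory
#'
#' Lays out `<id>_imu.csv` and `<id>_labels.csv` per recording plus a
#' `manifest.json` recording ids, per-recording seeds and the train/test
#' split.
#'
#' @param corpus A corpus from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in c(corpus$train, corpus$test)) {
    write_imu_csv(rec$stream, file.path(dir, paste0(rec$id, "_imu.csv")))
    write_labels_csv(rec$labels, file.path(dir, paste0(rec$id, "_labels.csv")))
  }
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#' @param dir Corpus directory.
#' @return A corpus list (`train`, `test`, `manifest`); recordings carry
#'   `stream`, `labels`, `id` (ground-truth `boundaries` are not persisted and
#'   are reconstructed from the labels).
#' @export
read_corpus <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(paste0("no manifest.json in ", dir))
  }
  manifest <- tibble::as_tibble(jsonlite::read_json(manifest_path,
                                                    simplifyVector = TRUE))
  load_rec <- function(id) {
    list(stream = read_imu_csv(file.path(dir, paste0(id, "_imu.csv"))),
         labels = read_labels_csv(file.path(dir, paste0(id, "_labels.csv"))),
         id = id)
  }
  list(
    train = lapply(manifest$id[manifest$split == "train"], load_rec),
    test = lapply(manifest$id[manifest$split == "test"], load_rec),
    manifest = manifest
  )
}

#' Ground-truth boundary frames from a per-frame label sequence
#' @param labels Integer per-frame class indices.
#' @param model The [motion_model()].
#' @return Tibble `label`, `frame` (0-based first occurrence of each boundary
#'   state; `NA` if absent).
#' @export
labels_to_boundaries <- function(labels, model) {
  bnd <- boundary_states(model)
  tibble::tibble(
    label = model$states$label[model$states$role == "boundary"],
    frame = vapply(bnd, function(k) {
      w <- which(labels == k)
      if (length(w) == 0) NA_integer_ else w[1] - 1L
    }, integer(1))
  )
}

#' Plot an IMU stream with optional state labels and boundaries
#'
#' Facets the six channels over time; shaded bands show the labeled motion
#' states and vertical lines mark boundary frames.
#'
#' @param stream Stream tibble.
#' @param labels Optional per-frame class indices.
#' @param boundaries Optional tibble `label`, `frame`.
#' @return A ggplot object.
#' @export
plot_imu_stream <- function(stream, labels = NULL, boundaries = NULL) {
  long <- tidyr::pivot_longer(stream, dplyr::all_of(imu_channel_cols),
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = imu_channel_cols)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y",
                        strip.position = "right")
  if (!is.null(labels)) {
    runs <- rle(labels != 0)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    act <- tibble::tibble(xmin = stream$frame[starts[runs$values]],
                          xmax = stream$frame[ends[runs$values]])
    if (nrow(act) > 0) {
      p <- p + ggplot2::geom_rect(
        data = act, inherit.aes = FALSE, alpha = 0.15, fill = "steelblue",
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf))
    }
  }
  p <- p + ggplot2::geom_line(linewidth = 0.3)
  if (!is.null(boundaries)) {
    p <- p + ggplot2::geom_vline(data = boundaries, linetype = "dashed",
                                 colour = "firebrick", linewidth = 0.3,
                                 ggplot2::aes(xintercept = .data$frame))
  }
  p + ggplot2::labs(x = "frame (10 ms)", y = NULL) + ggplot2::theme_minimal()
}
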