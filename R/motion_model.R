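#' Define a motion model as a chain of sub-motions with shared boundaries
#'
#' A sports motion is modeled as an ordered sequence of sub-motions (phases),
#' each divided into a *start*, a *performing*, and an *end* state. Transitions
#' between sub-motions are taken to be instantaneous, so every boundary state
#' occupies exactly one frame and the end state of a sub-motion is the same
#' state as the start state of the next. A model with `N` sub-motions therefore
#' has `2N + 1` distinct states, `N + 1` of which are boundary states, and the
#' per-timestep classifier built from it has `2N + 2` classes (class 0 is the
#' none/unknown state covering everything outside the motion).
#'
#' @param phases A data frame with one row per sub-motion, columns `phase`
#'   (sub-motion name), `start`, `performing`, `end` (state labels). Adjacent
#'   rows must chain: `end` of row `i` equals `start` of row `i + 1`.
#' @param name Name of the motion (e.g. `"soccer_kick"`).
#'
#' @return An object of class `motion_model`: a list with elements `name`,
#'   `phases` (tibble as supplied), `states` (tibble with one row per state:
#'   `label`, `index` (classifier class index, temporal order starting at 1),
#'   `role` (`"boundary"` or `"performing"`)), and `n_phases`.
#'
#' @examples
#' m <- motion_model(
#'   data.frame(
#'     phase = c("backswing", "swing"),
#'     start = c("ready", "top"),
#'     performing = c("going_back", "accelerating"),
#'     end = c("top", "impact")
#'   ),
#'   name = "demo_swing"
#' )
#' n_classes(m)        # 2 * 2 + 2 = 6
#' boundary_states(m)  # class indices of ready, top, impact
#' @export
motion_model <- function(phases, name = "motion") {
  phases <- tibble::as_tibble(phases)
  required <- c("phase", "start", "performing", "end")
  missing_cols <- setdiff(required, names(phases))
  if (length(missing_cols) > 0) {
    abort(paste0("`phases` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(phases) < 1) {
    abort("a motion model needs at least one phase")
  }
  phases <- phases[required]
  for (col in required) phases[[col]] <- as.character(phases[[col]])

  n <- nrow(phases)
  for (i in seq_len(n)) {
    trio <- unlist(phases[i, c("start", "performing", "end")], use.names = FALSE)
    if (anyDuplicated(trio)) {
      abort(paste0("phase '", phases$phase[i],
                   "': start, performing and end labels must be distinct"))
    }
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (phases$end[i] != phases$start[i + 1]) {
        abort(paste0(
          "broken boundary chain: end of phase '", phases$phase[i], "' is '",
          phases$end[i], "' but start of phase '", phases$phase[i + 1],
          "' is '", phases$start[i + 1], "'"
        ))
      }
    }
  }

  # temporal state order: s1, p1, e1(=s2), p2, e2(=s3), ..., pN, eN
  labels <- character(2 * n + 1)
  roles <- character(2 * n + 1)
  labels[1] <- phases$start[1]
  roles[1] <- "boundary"
  for (i in seq_len(n)) {
    labels[2 * i] <- phases$performing[i]
    roles[2 * i] <- "performing"
    labels[2 * i + 1] <- phases$end[i]
    roles[2 * i + 1] <- "boundary"
  }
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1]
    abort(paste0("duplicate state label '", dup,
                 "' (labels may be shared only across a phase boundary)"))
  }

  states <- tibble::tibble(
    label = labels,
    index = seq_along(labels),
    role = roles
  )
  structure(
    list(name = name, phases = phases, states = states, n_phases = n),
    class = "motion_model"
  )
}

#' @export
print.motion_model <- function(x, ...) {
  cat("<motion_model> ", x$name, "\n", sep = "")
  cat("  ", x$n_phases, " phase(s), ", nrow(x$states), " states, ",
      n_classes(x), " classifier classes (incl. none = 0)\n", sep = "")
  for (i in seq_len(x$n_phases)) {
    cat(sprintf("  %d. %s: [%s] %s [%s]\n", i, x$phases$phase[i],
                x$phases$start[i], x$phases$performing[i], x$phases$end[i]))
  }
  invisible(x)
}

#' Number of classifier classes of a motion model
#'
#' `2N + 2` for `N` phases: the `2N + 1` motion states plus the none/unknown
#' class (index 0).
#' @param model A [motion_model()].
#' @return Integer.
#' @export
n_classes <- function(model) {
  stopifnot(inherits(model, "motion_model"))
  nrow(model$states) + 1L
}

#' State label to class index mapping
#'
#' @param model A [motion_model()].
#' @return A named integer vector mapping every state label (plus `"none"`) to
#'   its classifier class index; `none = 0`, motion states numbered in temporal
#'   order starting at 1.
#' @export
state_index <- function(model) {
  stopifnot(inherits(model, "motion_model"))
  idx <- c(0L, model$states$index)
  names(idx) <- c("none", model$states$label)
  idx
}

#' Class indices of the boundary states, in temporal order
#'
#' A model with `N` phases has `N + 1` boundary states: the start of phase 1,
#' each shared inter-phase boundary, and the end of phase `N`. These are the
#' states whose temporal index is localized to a single frame by [segment_motion()].
#'
#' @param model A [motion_model()].
#' @return Integer vector of `N + 1` class indices, strictly increasing.
#' @export
boundary_states <- function(model) {
  stopifnot(inherits(model, "motion_model"))
  model$states$index[model$states$role == "boundary"]
}

#' Full expected temporal state pattern of a motion
#'
#' The sequence of class indices a single performance traverses:
#' `s1, p1, b12, p2, ..., eN` — length `2N + 1`, each shared boundary appearing
#' once. Restricting the pattern to boundary states gives [boundary_states()].
#'
#' @param model A [motion_model()].
#' @return Integer vector of class indices of length `2N + 1`.
#' @export
state_pattern <- function(model) {
  stopifnot(inherits(model, "motion_model"))
  model$states$index
}

#' Read / write a motion model definition file
#'
#' The on-disk format is declarative YAML: a `name` plus a `phases` list of
#' `{phase, start, performing, end}` entries. Two example definitions are
#' bundled: `soccer_kick.yaml` (5 phases, states LS1..LS11) and
#' `two_hand_throw.yaml` (3 phases, LT1..LT7); locate them with
#' `system.file("extdata", "soccer_kick.yaml", package = "motionseg")`.
#'
#' @param path Path to a YAML model definition.
#' @return `read_motion_model()` returns a [motion_model()];
#'   `write_motion_model()` returns `path` invisibly.
#' @export
read_motion_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model config not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$phases) || length(cfg$phases) == 0) {
    abort("model config has an empty phase list")
  }
  phases <- purrr::map_dfr(cfg$phases, function(p) {
    tibble::tibble(
      phase = p$phase %||% abort("phase entry missing 'phase' name"),
      start = p$start %||% abort("phase entry missing 'start'"),
      performing = p$performing %||% abort("phase entry missing 'performing'"),
      end = p$end %||% abort("phase entry missing 'end'")
    )
  })
  motion_model(phases, name = cfg$name %||% "motion")
}

#' @rdname read_motion_model
#' @param model A [motion_model()] to serialize.
#' @export
write_motion_model <- function(model, path) {
  stopifnot(inherits(model, "motion_model"))
  cfg <- list(
    name = model$name,
    phases = purrr::pmap(model$phases, function(phase, start, performing, end) {
      list(phase = phase, start = start, performing = performing, end = end)
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
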