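# Task environment: target displays, experimental conditions, geometry.
#
# Coordinate convention: metres, origin at the start position, x rightward,
# y away from the participant. The nominal layout is a 3 x 5 grid with 6 cm
# spacing whose first (proximal) row lies 6 cm from the start position, which
# sits at the central column.

GRID_SPACING <- 0.06
TARGET_RADII <- c(0.005, 0.008, 0.011)
TARGET_VALUES <- c(10, 12, 15)
JITTER_AMPLITUDE <- 0.011
N_TARGETS <- 15L
START_ID <- 15L # 0-based id used for the start position in distance matrices

CONDITION_NAMES <- c("size", "value", "small_high", "small_low")

#' Size-value pairings for an experimental condition
#'
#' Each condition pairs the three radius tiers (5, 8, 11 mm) with the three
#' point values (10, 12, 15) in a specific way; five targets of each pairing
#' appear in every display. In the `size` condition only size varies (value
#' fixed at 12 points); in the `value` condition only value varies (radius
#' fixed at 8 mm); `small_high` anti-correlates size and value (smallest
#' targets are most valuable) and `small_low` correlates them.
#'
#' @param condition One of `"size"`, `"value"`, `"small_high"`, `"small_low"`.
#' @return A data frame with columns `radius` (m) and `value` (points), one
#'   row per pairing (3 rows).
#' @export
condition_pairings <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% CONDITION_NAMES) {
    stopf("unknown condition %s; must be one of %s",
          deparse(condition), paste(CONDITION_NAMES, collapse = ", "))
  }
  switch(condition,
    size       = data.frame(radius = TARGET_RADII, value = c(12, 12, 12)),
    value      = data.frame(radius = rep(0.008, 3), value = TARGET_VALUES),
    small_high = data.frame(radius = TARGET_RADII, value = c(15, 12, 10)),
    small_low  = data.frame(radius = TARGET_RADII, value = c(10, 12, 15))
  )
}

# Nominal 3x5 grid node coordinates (slot order row-major, proximal row first).
grid_nodes <- function() {
  xs <- (-2:2) * GRID_SPACING
  ys <- GRID_SPACING + (0:2) * GRID_SPACING
  data.frame(
    x = rep(xs, times = 3),
    y = rep(ys, each = 5)
  )
}

#' Generate a randomized 15-target display
#'
#' Builds one trial display: 15 circular targets on a 3 x 5 grid (6 cm
#' spacing) with independent per-axis uniform positional jitter, and the
#' condition's three size-value pairings assigned to five targets each, with
#' the pairing-to-slot assignment permuted uniformly at random per trial.
#'
#' @param condition Condition name (see [condition_pairings()]).
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream (the caller's stream is untouched when a seed is given).
#' @param jitter Per-axis jitter amplitude in metres (uniform on
#'   `[-jitter, jitter]`); default 0.011. Set 0 for exact grid placement.
#' @param trial_id Integer trial identifier stored on the display.
#' @return An object of class `forage_display`: a list with `targets` (data
#'   frame: `id` 0-14, `x`, `y`, `radius`, `value`, `harvested`), `condition`,
#'   `start` (length-2 numeric, always `c(0, 0)`), and `trial_id`.
#' @export
generate_display <- function(condition, seed = NULL, jitter = JITTER_AMPLITUDE,
                             trial_id = 1L) {
  pair <- condition_pairings(condition)
  stopifnot(is.numeric(jitter), length(jitter) == 1L, jitter >= 0)
  with_seed(seed, {
    nodes <- grid_nodes()
    perm <- sample.int(N_TARGETS) # pairing label for each grid slot
    lab <- rep(seq_len(3L), each = 5L)[perm]
    targets <- data.frame(
      id = 0:(N_TARGETS - 1L),
      x = nodes$x + runif(N_TARGETS, -jitter, jitter),
      y = nodes$y + runif(N_TARGETS, -jitter, jitter),
      radius = pair$radius[lab],
      value = pair$value[lab],
      harvested = FALSE
    )
    new_display(targets, condition, trial_id)
  })
}

new_display <- function(targets, condition, trial_id) {
  structure(
    list(targets = targets, condition = condition,
         start = c(0, 0), trial_id = as.integer(trial_id)),
    class = "forage_display"
  )
}

validate_display <- function(display) {
  if (!inherits(display, "forage_display")) stopf("not a forage_display")
  t <- display$targets
  if (nrow(t) != N_TARGETS) {
    stopf("display for trial %d has %d targets; exactly 15 required",
          display$trial_id, nrow(t))
  }
  if (!all(t$radius %in% TARGET_RADII)) stopf("invalid target radius")
  if (!all(t$value %in% TARGET_VALUES)) stopf("invalid target value")
  invisible(display)
}

#' @export
print.forage_display <- function(x, ...) {
  cat(sprintf("<forage_display> trial %d, condition '%s', %d/%d harvested\n",
              x$trial_id, x$condition, sum(x$targets$harvested), N_TARGETS))
  invisible(x)
}

#' Center-to-center distance matrix for a display
#'
#' @param display A `forage_display`.
#' @return A 16 x 16 symmetric matrix of Euclidean distances in metres.
#'   Rows/columns 1-15 are targets with ids 0-14 in order; row/column 16 is
#'   the start position (id 15).
#' @export
distance_matrix <- function(display) {
  validate_display(display)
  xy <- rbind(as.matrix(display$targets[, c("x", "y")]),
              matrix(display$start, nrow = 1))
  m <- as.matrix(stats::dist(xy))
  dimnames(m) <- list(0:START_ID, 0:START_ID)
  m
}

#' Legal next harvest targets
#'
#' In the free task every non-harvested target may be chosen. In the
#' constrained task, harvests must proceed in non-increasing value order, so
#' only non-harvested targets whose value equals the maximum value among the
#' remaining targets are legal.
#'
#' @param display A `forage_display` (its `harvested` flags define state).
#' @param constrained Logical; apply the decreasing-value rule?
#' @return Integer vector of legal target ids (0-based); empty when all
#'   targets are harvested.
#' @export
legal_next_targets <- function(display, constrained = FALSE) {
  validate_display(display)
  t <- display$targets
  open <- t$id[!t$harvested]
  if (length(open) == 0L || !constrained) return(open)
  vals <- t$value[!t$harvested]
  open[vals == max(vals)]
}

#' Mark targets as harvested
#'
#' @param display A `forage_display`.
#' @param ids Integer target ids (0-based) to flag as harvested.
#' @return The updated display.
#' @export
mark_harvested <- function(display, ids) {
  validate_display(display)
  if (length(ids)) {
    idx <- match(ids, display$targets$id)
    if (anyNA(idx)) stopf("unknown target id(s): %s",
                          paste(ids[is.na(idx)], collapse = ", "))
    display$targets$harvested[idx] <- TRUE
  }
  display
}
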