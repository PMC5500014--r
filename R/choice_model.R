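# Cost/softmax choice model. The cost of taking target j next from target i
# combines the negative reward rate (value over predicted movement time), a
# power-law distance penalty and a size penalty:
#
#   c_ij = -r_ij + w1 * d_ij^gamma - w2 * s_j,   r_ij = v_j / t_ij
#
# with d_ij in metres and s_j the target radius in metres. An n-look-ahead
# cost adds the temporally discounted, minimum-over-continuations future step
# costs (weights lambda_1..lambda_{n-1}); a softmax with precision beta maps
# candidate costs to choice probabilities.

#' Choice model parameter set
#'
#' @param beta Softmax precision (>= 0); 0 yields uniform choice.
#' @param w1 Distance-penalty weight (units bound to metres via `gamma`).
#' @param gamma Distance exponent (> 0).
#' @param w2 Size-penalty weight (radius in metres; positive values favour
#'   larger targets).
#' @param lambdas Numeric vector of `lookahead_n - 1` discount weights for
#'   future steps.
#' @param lookahead_n Look-ahead depth, 1-5 (1 = immediate harvest only).
#' @param include_reward_rate,include_distance,include_size Logical flags
#'   switching the three cost components (submodels set one to `FALSE`).
#' @return An object of class `choice_params`.
#' @export
choice_params <- function(beta, w1 = 0, gamma = 1, w2 = 0,
                          lambdas = numeric(0), lookahead_n = 1L,
                          include_reward_rate = TRUE,
                          include_distance = TRUE,
                          include_size = TRUE) {
  lookahead_n <- as.integer(lookahead_n)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stopf("beta must be a scalar >= 0")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stopf("gamma must be a scalar > 0")
  if (lookahead_n < 1L || lookahead_n > 5L)
    stopf("lookahead_n must be in 1..5")
  if (length(lambdas) != lookahead_n - 1L)
    stopf("length(lambdas) must equal lookahead_n - 1 (= %d)", lookahead_n - 1L)
  structure(
    list(beta = beta, w1 = w1, gamma = gamma, w2 = w2,
         lambdas = as.numeric(lambdas), lookahead_n = lookahead_n,
         include_reward_rate = isTRUE(include_reward_rate),
         include_distance = isTRUE(include_distance),
         include_size = isTRUE(include_size)),
    class = "choice_params"
  )
}

#' @export
print.choice_params <- function(x, ...) {
  cat(sprintf(
    "<choice_params> beta=%.4g w1=%.4g gamma=%.4g w2=%.4g n=%d lambdas=(%s)\n",
    x$beta, x$w1, x$gamma, x$w2, x$lookahead_n,
    paste(signif(x$lambdas, 4), collapse = ", ")))
  flags <- c("reward_rate", "distance", "size")[
    c(x$include_reward_rate, x$include_distance, x$include_size)]
  cat("  components:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' Reward rate of a candidate harvest
#'
#' @param value Target value in points.
#' @param predicted_time Predicted movement time in seconds (> 0).
#' @return Points per second, `value / predicted_time`.
#' @export
reward_rate <- function(value, predicted_time) {
  if (any(predicted_time <= 0)) stopf("predicted_time must be positive")
  value / predicted_time
}

# Per-display geometry/timing context: distance matrix (16x16), predicted
# time and reward-rate matrices (origin 0..15 x target 0..14), radii, values.
display_context <- function(display, movement_model) {
  validate_display(display)
  d <- distance_matrix(display)
  s <- display$targets$radius
  v <- display$targets$value
  tmat <- matrix(0, 16, N_TARGETS)
  for (j in seq_len(N_TARGETS)) {
    tmat[, j] <- predict_time(movement_model, d[, j], s[j])
  }
  rmat <- sweep(1 / tmat, 2, v, `*`)
  list(d = d[, seq_len(N_TARGETS), drop = FALSE], dfull = d,
       tmat = tmat, rmat = rmat, s = s, v = v)
}

# Normalise an origin spec ("start" or 0-based id 0..15) to a 0-based index.
origin_index <- function(origin) {
  if (identical(origin, "start")) return(START_ID)
  origin <- as.integer(origin)
  if (origin < 0L || origin > START_ID) stopf("origin must be 0..15 or 'start'")
  origin
}

#' Immediate (one-step) cost of a candidate harvest
#'
#' @param params A `choice_params`.
#' @param origin Origin id: 0-based target id, 15 or `"start"` for the start
#'   position.
#' @param candidate Candidate target id(s), 0-based.
#' @param display A `forage_display`.
#' @param movement_model A `movement_time_model`.
#' @return Numeric cost(s) `c_ij`, named by candidate id.
#' @export
step_cost <- function(params, origin, candidate, display, movement_model) {
  stopifnot(inherits(params, "choice_params"))
  ctx <- display_context(display, movement_model)
  i <- origin_index(origin) + 1L
  j <- as.integer(candidate) + 1L
  if (any(j < 1L | j > N_TARGETS)) stopf("candidate ids must be 0..14")
  cost <- -ctx$rmat[i, j] * params$include_reward_rate +
    params$w1 * ctx$d[i, j]^params$gamma * params$include_distance -
    params$w2 * ctx$s[j] * params$include_size
  setNames(cost, candidate)
}

#' Look-ahead cost of candidate harvests
#'
#' For each candidate j, the minimum over ordered continuations of distinct
#' unharvested targets (length `lookahead_n - 1`, truncated to the remaining
#' count) of the immediate cost plus the lambda-discounted future step costs.
#' With `lookahead_n = 1` this equals [step_cost()].
#'
#' @inheritParams step_cost
#' @param candidates Candidate ids; default all unharvested targets.
#' @return Numeric vector of costs `C_j` named by candidate id.
#' @export
lookahead_cost <- function(params, origin, display, movement_model,
                           candidates = NULL) {
  stopifnot(inherits(params, "choice_params"))
  ctx <- display_context(display, movement_model)
  avail <- legal_next_targets(display, constrained = FALSE)
  if (is.null(candidates)) candidates <- avail
  candidates <- as.integer(candidates)
  if (!all(candidates %in% avail)) stopf("candidates must be unharvested")
  cost <- cpp_lookahead_costs(
    ctx$dfull, ctx$rmat, ctx$s, origin_index(origin),
    candidates, avail,
    params$w1, params$gamma, params$w2,
    params$include_reward_rate, params$include_distance, params$include_size,
    params$lambdas, params$lookahead_n)
  setNames(cost, candidates)
}

#' Softmax choice probabilities over legal candidates
#'
#' `P_j = exp(-beta * C_j) / sum_j exp(-beta * C_j)` over the legal candidate
#' set, computed with max-subtraction for numerical stability.
#'
#' @inheritParams step_cost
#' @param constrained Logical; restrict candidates to the decreasing-value
#'   rule of the constrained task.
#' @return Named numeric vector of probabilities (names are candidate ids),
#'   summing to 1.
#' @export
choice_probabilities <- function(params, origin, display, movement_model,
                                 constrained = FALSE) {
  cand <- legal_next_targets(display, constrained = constrained)
  if (length(cand) == 0L) stopf("no legal candidates: all targets harvested")
  C <- lookahead_cost(params, origin, display, movement_model,
                      candidates = cand)
  z <- -params$beta * C
  z <- z - max(z)
  p <- exp(z)
  p / sum(p)
}

# ---- Session data ----------------------------------------------------------

#' Assemble a session
#'
#' A session is the unit of fitting: one (simulated or recorded) participant's
#' trials, each a display plus the ordered harvest records.
#'
#' @param trials List of trials; each a list with `display`
#'   (`forage_display`, fresh flags) and `harvests` (data frame with columns
#'   `trial_id`, `harvest_index` (1-based), `chosen` (target id),
#'   `origin` (previous target id or 15 for start), `time` (s)).
#' @param effector `"hand"` or `"eye"`.
#' @param movement_model The session's `movement_time_model`.
#' @param constrained Logical; was the session run under the decreasing-value
#'   constraint?
#' @param agent_kind Optional label of the generating agent.
#' @param seed Optional generating seed (metadata).
#' @return An object of class `forage_session`.
#' @export
forage_session <- function(trials, effector = c("hand", "eye"),
                           movement_model = default_movement_model(effector),
                           constrained = FALSE, agent_kind = NA_character_,
                           seed = NA_integer_) {
  effector <- match.arg(effector)
  for (tr in trials) {
    validate_display(tr$display)
    h <- tr$harvests
    if (nrow(h) > 0) {
      if (any(diff(h$harvest_index) != 1L) || h$harvest_index[1] != 1L)
        stopf("trial %d: harvest records must be consecutive from 1",
              tr$display$trial_id)
      if (anyDuplicated(h$chosen))
        stopf("trial %d: a target was harvested twice", tr$display$trial_id)
    }
  }
  structure(
    list(trials = trials, effector = effector,
         movement_model = movement_model, constrained = constrained,
         agent_kind = agent_kind, seed = seed),
    class = "forage_session"
  )
}

#' @export
print.forage_session <- function(x, ...) {
  nh <- vapply(x$trials, function(tr) nrow(tr$harvests), integer(1))
  cat(sprintf(
    "<forage_session> %s, %d trials, %.1f harvests/trial%s (agent: %s)\n",
    x$effector, length(x$trials), mean(nh),
    if (x$constrained) ", constrained" else "", x$agent_kind))
  invisible(x)
}

# Precompute the likelihood context: per-display matrices plus one entry per
# scored choice (harvests 2..8; harvest 1 is never scored), flattened into
# integer vectors with offset pointers. Choices stay grouped by display so
# the C++ evaluator rebuilds the cost matrix only on display changes.
session_context <- function(session, max_harvest = 8L) {
  stopifnot(inherits(session, "forage_session"))
  displays <- list()
  disp <- origin <- chosen <- integer(0)
  avail_l <- list(); cand_l <- list()
  for (ti in seq_along(session$trials)) {
    tr <- session$trials[[ti]]
    h <- tr$harvests
    if (nrow(h) < 2L) next
    ctx <- display_context(tr$display, session$movement_model)
    displays[[length(displays) + 1L]] <-
      list(d = ctx$dfull, r = ctx$rmat, s = ctx$s)
    di <- length(displays)
    vals <- tr$display$targets$value
    for (k in 2:min(nrow(h), max_harvest)) {
      prior <- h$chosen[seq_len(k - 1L)]
      avail <- setdiff(0:(N_TARGETS - 1L), prior)
      cand <- avail
      if (session$constrained) {
        mx <- max(vals[avail + 1L])
        cand <- avail[vals[avail + 1L] == mx]
      }
      disp <- c(disp, di)
      origin <- c(origin, h$chosen[k - 1L])
      chosen <- c(chosen, h$chosen[k])
      avail_l[[length(avail_l) + 1L]] <- as.integer(avail)
      cand_l[[length(cand_l) + 1L]] <- as.integer(cand)
    }
  }
  list(displays = displays, disp = disp, origin = origin, chosen = chosen,
       avail_v = unlist(avail_l) %||% integer(0),
       avail_p = c(0L, cumsum(lengths(avail_l))),
       cand_v = unlist(cand_l) %||% integer(0),
       cand_p = c(0L, cumsum(lengths(cand_l))),
       n = length(disp))
}

context_loglik <- function(ctx, params) {
  if (ctx$n == 0L) stopf("session has no scored choices")
  cpp_session_loglik(
    ctx$displays, ctx$disp, ctx$origin, ctx$chosen,
    ctx$avail_v, ctx$avail_p, ctx$cand_v, ctx$cand_p,
    params$beta, params$w1, params$gamma, params$w2,
    params$include_reward_rate, params$include_distance, params$include_size,
    params$lambdas, params$lookahead_n)
}

#' Session log-likelihood of the choice model
#'
#' Sums `log P(chosen target)` over the scored choices of every trial:
#' harvests 2 through `max_harvest` (default 8), all conditions pooled. The
#' first harvest of each trial is never scored.
#'
#' @param params A `choice_params`.
#' @param session A `forage_session`.
#' @param max_harvest Last harvest index scored per trial (default 8).
#' @return The log-likelihood (scalar) with attribute `n`, the number of
#'   scored choices.
#' @export
session_log_likelihood <- function(params, session, max_harvest = 8L) {
  stopifnot(inherits(params, "choice_params"))
  ctx <- session_context(session, max_harvest = max_harvest)
  ll <- context_loglik(ctx, params)
  if (!is.finite(ll)) stopf("a scored choice has probability 0 under params")
  structure(ll, n = ctx$n)
}
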