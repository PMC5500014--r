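# Synthetic-data engine: simulated agents harvesting displays under the
# 3.25 s trial clock, the rate-maximising optimal planner, and efficiency
# ratios of an agent's performance relative to the planner's on the same
# displays.

AGENT_KINDS <- c("model", "uniform", "greedy", "planner")

#' Specify a simulated agent
#'
#' @param kind `"model"` (samples from the choice model's softmax),
#'   `"uniform"` (equiprobable over legal targets), `"greedy"` (max immediate
#'   reward rate) or `"planner"` (first element of the optimal planner's
#'   sequence, re-planned every harvest).
#' @param params `choice_params` (required for the model agent).
#' @param effector `"hand"` or `"eye"`.
#' @param time_budget Trial duration in seconds (default 3.25).
#' @param time_noise_sd SD of Gaussian inter-harvest time noise in seconds
#'   (truncated below at 0.05 s); 0 for noiseless timing.
#' @param constrained Logical; enforce the decreasing-value harvest order.
#' @param planner_depth Planner look-ahead depth (planner agent; default 5).
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(kind = AGENT_KINDS, params = NULL,
                       effector = c("hand", "eye"), time_budget = 3.25,
                       time_noise_sd = 0.08, constrained = FALSE,
                       planner_depth = 5L) {
  kind <- match.arg(kind)
  effector <- match.arg(effector)
  stopifnot(time_budget > 0, time_noise_sd >= 0)
  if (kind == "model") {
    if (!inherits(params, "choice_params"))
      stopf("model agent requires `params` (choice_params)")
  }
  structure(
    list(kind = kind, params = params, effector = effector,
         time_budget = time_budget, time_noise_sd = time_noise_sd,
         constrained = constrained, planner_depth = as.integer(planner_depth)),
    class = "agent_spec"
  )
}

# Truncated-Gaussian inter-harvest time (lower bound 0.05 s), sampled by
# inverse CDF so each draw consumes exactly one uniform from the stream.
draw_time <- function(t_pred, sd) {
  if (sd <= 0) return(t_pred)
  lo <- pnorm(0.05, mean = t_pred, sd = sd)
  if (lo >= 1) return(0.05)
  qnorm(runif(1, lo, 1), mean = t_pred, sd = sd)
}

#' Simulate one trial
#'
#' Starting at the start position, the agent repeatedly selects a legal
#' target (per its policy), the movement takes the predicted time plus
#' truncated-Gaussian noise, and the trial ends when the next harvest would
#' overrun the time budget (the overrunning harvest does not count). Draws
#' from the current RNG stream.
#'
#' @param agent An `agent_spec`.
#' @param display A fresh `forage_display` (no harvested flags set).
#' @param movement_model A `movement_time_model`.
#' @return A list with `harvests` (data frame: `trial_id`, `harvest_index`,
#'   `chosen`, `origin`, `time`) and `points` (total harvested).
#' @export
simulate_trial <- function(agent, display, movement_model) {
  stopifnot(inherits(agent, "agent_spec"))
  validate_display(display)
  if (any(display$targets$harvested)) stopf("display must be fresh")
  ctx <- display_context(display, movement_model)
  origin <- START_ID
  elapsed <- 0
  rec <- list()
  points <- 0
  repeat {
    cand <- legal_next_targets(display, constrained = agent$constrained)
    if (length(cand) == 0L) break
    j <- switch(agent$kind,
      uniform = cand[sample.int(length(cand), 1L)],
      greedy = {
        rr <- ctx$rmat[origin + 1L, cand + 1L]
        cand[which.max(rr)] # which.max takes the lowest id on ties
      },
      model = {
        p <- choice_probabilities(agent$params, origin, display,
                                  movement_model,
                                  constrained = agent$constrained)
        as.integer(names(p))[sample.int(length(p), 1L, prob = p)]
      },
      planner = {
        pc <- optimal_planner_choice(display, movement_model,
                                     remaining_time = agent$time_budget -
                                       elapsed,
                                     depth = agent$planner_depth,
                                     origin = origin)
        if (length(pc$sequence) == 0L) break
        pc$sequence[1L]
      })
    t <- draw_time(ctx$tmat[origin + 1L, j + 1L], agent$time_noise_sd)
    if (elapsed + t > agent$time_budget) break
    elapsed <- elapsed + t
    rec[[length(rec) + 1L]] <- data.frame(
      trial_id = display$trial_id, harvest_index = length(rec) + 1L,
      chosen = j, origin = origin, time = t)
    points <- points + display$targets$value[j + 1L]
    display <- mark_harvested(display, j)
    origin <- j
  }
  harvests <- if (length(rec)) do.call(rbind, rec) else
    data.frame(trial_id = integer(0), harvest_index = integer(0),
               chosen = integer(0), origin = integer(0), time = numeric(0))
  list(harvests = harvests, points = points)
}

#' Optimal rate-maximising planner choice
#'
#' Enumerates ordered sequences of unharvested targets up to `depth` long,
#' truncating each at the prefix whose predicted cumulative time fits within
#' the remaining trial time, and maximises the rate of reward given the
#' remaining time: because that time is fixed, the best feasible prefix is
#' the one harvesting the most points, with ties broken by shorter predicted
#' duration, then fewer targets, then lowest first target id. Only the first
#' target of the returned sequence is committed per harvest; the planner
#' re-plans at every step.
#'
#' @param display A `forage_display` (harvested flags define state).
#' @param movement_model A `movement_time_model`.
#' @param remaining_time Remaining trial time in seconds (> 0).
#' @param depth Maximum sequence length (default 5).
#' @param origin Origin id (0-based target id or 15/`"start"`).
#' @return A list of class `planner_choice`: `sequence` (ordered target
#'   ids), `points`, `time` (predicted, s) and `rate` (points/s). When not
#'   even one harvest fits, `sequence` is empty and `rate` is `NA`.
#' @export
optimal_planner_choice <- function(display, movement_model, remaining_time,
                                   depth = 5L, origin = "start") {
  validate_display(display)
  stopifnot(remaining_time > 0)
  avail <- legal_next_targets(display, constrained = FALSE)
  if (length(avail) == 0L) stopf("no unharvested targets to plan over")
  ctx <- display_context(display, movement_model)
  out <- cpp_planner_choice(ctx$tmat, ctx$v, as.integer(avail),
                            origin_index(origin), remaining_time,
                            as.integer(depth))
  structure(out, class = "planner_choice")
}

#' Generate a full synthetic session
#'
#' Free-task sessions run 4 conditions (size, value, small-high, small-low)
#' of `trials_per_condition` trials each; constrained sessions run 3 (the
#' size condition is dropped because all its targets share one value). Fully
#' reproducible from `seed`.
#'
#' @param agent An `agent_spec`.
#' @param movement_model Movement-time model used both to simulate times and
#'   stored on the session; defaults to the effector's default coefficients.
#' @param conditions Character vector of condition names; `NULL` picks the
#'   task's standard set.
#' @param trials_per_condition Trials per condition (default 50).
#' @param seed Integer seed.
#' @param jitter Display jitter amplitude in metres.
#' @return A `forage_session`.
#' @export
generate_session <- function(agent,
                             movement_model =
                               default_movement_model(agent$effector),
                             conditions = NULL, trials_per_condition = 50L,
                             seed = 1L, jitter = JITTER_AMPLITUDE) {
  stopifnot(inherits(agent, "agent_spec"))
  if (is.null(conditions)) {
    conditions <- if (agent$constrained)
      c("value", "small_high", "small_low") else CONDITION_NAMES
  }
  trials <- with_seed(seed, {
    out <- vector("list", length(conditions) * trials_per_condition)
    tid <- 0L
    for (cond in conditions) {
      for (k in seq_len(trials_per_condition)) {
        tid <- tid + 1L
        disp <- generate_display(cond, seed = NULL, jitter = jitter,
                                 trial_id = tid)
        sim <- simulate_trial(agent, disp, movement_model)
        out[[tid]] <- list(display = disp, harvests = sim$harvests,
                           points = sim$points)
      }
    }
    out
  })
  forage_session(trials, effector = agent$effector,
                 movement_model = movement_model,
                 constrained = agent$constrained,
                 agent_kind = agent$kind, seed = seed)
}

#' Re-run the optimal planner on a session's displays
#'
#' Rolls the planner (noiseless predicted times) over every display of
#' `session`, producing the matched optimal sessions used by
#' [efficiency_ratios()].
#'
#' @param session A `forage_session`.
#' @param depth Planner depth (default 5).
#' @param time_budget Trial duration (default 3.25 s).
#' @return A `forage_session` of planner trials on identical displays.
#' @export
planner_session <- function(session, depth = 5L, time_budget = 3.25) {
  stopifnot(inherits(session, "forage_session"))
  agent <- agent_spec("planner", effector = session$effector,
                      time_budget = time_budget, time_noise_sd = 0,
                      constrained = session$constrained,
                      planner_depth = depth)
  trials <- lapply(session$trials, function(tr) {
    disp <- tr$display
    disp$targets$harvested <- FALSE
    sim <- simulate_trial(agent, disp, session$movement_model)
    list(display = disp, harvests = sim$harvests, points = sim$points)
  })
  forage_session(trials, effector = session$effector,
                 movement_model = session$movement_model,
                 constrained = session$constrained,
                 agent_kind = "planner", seed = session$seed)
}

#' Efficiency ratios relative to the optimal planner
#'
#' Mean over trials of the actual-to-planner points ratio and harvest-count
#' ratio, on identical displays. Trials where the planner scores 0 are
#' excluded (their number is reported).
#'
#' @param session The actual (or simulated-agent) `forage_session`.
#' @param planner_sessions The matched planner session ([planner_session()]).
#' @return A list with `points_ratio`, `count_ratio` and `n_excluded`.
#' @export
efficiency_ratios <- function(session, planner_sessions) {
  stopifnot(inherits(session, "forage_session"),
            inherits(planner_sessions, "forage_session"),
            length(session$trials) == length(planner_sessions$trials))
  pts_a <- vapply(session$trials, function(tr) tr$points %||%
                    sum_points(tr), numeric(1))
  pts_p <- vapply(planner_sessions$trials, function(tr) tr$points %||%
                    sum_points(tr), numeric(1))
  cnt_a <- vapply(session$trials, function(tr) nrow(tr$harvests), numeric(1))
  cnt_p <- vapply(planner_sessions$trials, function(tr) nrow(tr$harvests),
                  numeric(1))
  same <- vapply(seq_along(session$trials), function(i) {
    isTRUE(all.equal(session$trials[[i]]$display$targets[, c("x", "y")],
                     planner_sessions$trials[[i]]$display$targets[, c("x", "y")],
                     tolerance = 1e-9))
  }, logical(1))
  if (!all(same)) stopf("sessions do not share displays")
  keep <- pts_p > 0
  if (any(!keep)) warning(sprintf("%d trial(s) with planner score 0 excluded",
                                  sum(!keep)))
  list(points_ratio = mean(pts_a[keep] / pts_p[keep]),
       count_ratio = mean(cnt_a[keep] / cnt_p[keep]),
       n_excluded = sum(!keep))
}

sum_points <- function(tr) {
  if (nrow(tr$harvests) == 0L) return(0)
  sum(tr$display$targets$value[tr$harvests$chosen + 1L])
}
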