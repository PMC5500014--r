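# Independent naive oracles (pure R, brute-force enumeration) and small
# fixture builders. The oracles deliberately share no code with the package's
# C++ enumeration paths.

# One-step cost computed directly from display geometry.
oracle_step_cost <- function(params, origin, j, display, movement_model) {
  t <- display$targets
  coord <- rbind(as.matrix(t[, c("x", "y")]), matrix(display$start, nrow = 1))
  d <- sqrt(sum((coord[origin + 1L, ] - coord[j + 1L, ])^2))
  tt <- predict_time(movement_model, d, t$radius[j + 1L])
  -(t$value[j + 1L] / tt) * params$include_reward_rate +
    params$w1 * d^params$gamma * params$include_distance -
    params$w2 * t$radius[j + 1L] * params$include_size
}

# Naive recursive look-ahead cost: exhaustive enumeration of all ordered
# continuations of distinct unharvested targets.
oracle_lookahead_cost <- function(params, origin, display, movement_model,
                                  candidates = NULL) {
  t <- display$targets
  avail <- t$id[!t$harvested]
  if (is.null(candidates)) candidates <- avail
  horizon <- min(params$lookahead_n, length(avail))
  lam <- params$lambdas[seq_len(max(horizon - 1L, 0L))]
  rec <- function(prev, remaining, lam) {
    if (length(lam) == 0L) return(0)
    best <- Inf
    for (k in remaining) {
      v <- lam[1] * oracle_step_cost(params, prev, k, display,
                                     movement_model) +
        rec(k, setdiff(remaining, k), lam[-1])
      if (v < best) best <- v
    }
    if (is.finite(best)) best else 0
  }
  vapply(candidates, function(j) {
    oracle_step_cost(params, origin, j, display, movement_model) +
      rec(j, setdiff(avail, j), lam)
  }, numeric(1))
}

# Naive planner: enumerate every ordered prefix (length <= depth) of
# unharvested targets whose predicted cumulative time fits the budget; pick
# the prefix with the most points (= max reward rate given the fixed
# remaining time), ties to shorter duration, then fewer targets, then lowest
# first id.
oracle_planner <- function(display, movement_model, remaining_time,
                           depth = 5L, origin = 15L) {
  t <- display$targets
  coord <- rbind(as.matrix(t[, c("x", "y")]), matrix(display$start, nrow = 1))
  avail <- t$id[!t$harvested]
  step_t <- function(i, j) {
    d <- sqrt(sum((coord[i + 1L, ] - coord[j + 1L, ])^2))
    predict_time(movement_model, d, t$radius[j + 1L])
  }
  best <- list(rate = -Inf, seq = integer(0), pts = -1, time = Inf)
  rec <- function(prev, remaining, seq, t_acc, p_acc) {
    if (length(seq) >= depth) return()
    for (k in remaining) {
      t2 <- t_acc + step_t(prev, k)
      if (t2 > remaining_time) next
      p2 <- p_acc + t$value[k + 1L]
      s2 <- c(seq, k)
      b <- best
      if (p2 > b$pts ||
          (p2 == b$pts && (t2 < b$time - 1e-12 ||
            (t2 <= b$time + 1e-12 && (length(s2) < length(b$seq) ||
              (length(s2) == length(b$seq) && s2[1] < b$seq[1])))))) {
        best <<- list(rate = p2 / t2, seq = s2, pts = p2, time = t2)
      }
      rec(k, setdiff(remaining, k), s2, t2, p2)
    }
  }
  rec(origin, avail, integer(0), 0, 0)
  if (best$pts < 0) best <- list(rate = NA, seq = integer(0), pts = 0, time = 0)
  best
}

# Deterministic small fixtures -----------------------------------------------

zero_jitter_display <- function(condition = "small_high", seed = 1,
                                trial_id = 1L) {
  generate_display(condition, seed = seed, jitter = 0, trial_id = trial_id)
}

hand_model <- function(sigma = 0) {
  movement_time_model("hand", slope = 1.0, intercept = 0.2, sigma = sigma)
}

# Reference 1-ahead generator parameters used across fitting tests.
reference_params <- function() {
  choice_params(beta = 0.05, w1 = 500, gamma = 1, w2 = 300)
}

small_session <- function(params = reference_params(),
                          trials_per_condition = 5L, seed = 99L,
                          effector = "hand", constrained = FALSE) {
  generate_session(
    agent_spec("model", params = params, effector = effector,
               constrained = constrained),
    trials_per_condition = trials_per_condition, seed = seed)
}
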