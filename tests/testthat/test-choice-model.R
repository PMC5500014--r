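test_that("reward rate and step cost match direct evaluation", {
  expect_equal(reward_rate(12, 1.0), 12.0)
  expect_equal(reward_rate(15, 0.26), 15 / 0.26)
  expect_equal(reward_rate(10, 0.354), 10 / 0.354)
  expect_error(reward_rate(10, 0), "positive")

  d <- zero_jitter_display("small_high", seed = 3)
  mm <- hand_model()

  # all component flags off -> zero cost everywhere
  p0 <- choice_params(beta = 1, include_reward_rate = FALSE,
                      include_distance = FALSE, include_size = FALSE)
  expect_true(all(step_cost(p0, "start", 0:14, d, mm) == 0))

  # reward-rate-only cost is -v/t
  pr <- choice_params(beta = 1, include_distance = FALSE,
                      include_size = FALSE)
  j <- d$targets$id[d$targets$value == 15][1]
  dist <- sqrt(sum((as.matrix(d$targets[j + 1, c("x", "y")]) - d$start)^2))
  expect_equal(unname(step_cost(pr, "start", j, d, mm)),
               -15 / (0.2 + 1.0 * dist))

  # distance-only with w1=100, gamma=1 at d=0.06 -> 6.0
  pd <- choice_params(beta = 1, w1 = 100, gamma = 1,
                      include_reward_rate = FALSE, include_size = FALSE)
  t <- d$targets
  pair <- which(abs(outer(t$x, t$x, "-") - 0.06) < 1e-9 &
                  abs(outer(t$y, t$y, "-")) < 1e-9, arr.ind = TRUE)[1, ]
  expect_equal(unname(step_cost(pd, pair[2] - 1L, pair[1] - 1L, d, mm)), 6.0)

  # full cost agrees with the independent oracle across all candidates
  pf <- choice_params(beta = 0.05, w1 = 500, gamma = 1.3, w2 = 300)
  got <- step_cost(pf, 4L, setdiff(0:14, 4L), d, mm)
  want <- vapply(setdiff(0:14, 4L), function(jj)
    oracle_step_cost(pf, 4L, jj, d, mm), numeric(1))
  expect_equal(unname(got), want)
})

test_that("lookahead cost equals the naive recursive enumerator", {
  mm <- hand_model()
  set.seed(42)
  for (rep in 1:6) {
    d <- generate_display(sample(c("size", "value", "small_high"), 1),
                          seed = NULL)
    n_remaining <- sample(3:8, 1)
    d <- mark_harvested(d, sample(0:14, 15 - n_remaining))
    origin <- sample(c(legal_next_targets(d), 15L), 1) # target or start
    if (origin %in% legal_next_targets(d)) {
      d <- mark_harvested(d, origin)
      if (sum(!d$targets$harvested) == 0) next
    }
    n <- sample(1:5, 1)
    lam <- if (n > 1) runif(n - 1, -0.5, 1) else numeric(0)
    p <- choice_params(beta = 0.05, w1 = runif(1, 0, 800),
                       gamma = runif(1, 0.4, 2), w2 = runif(1, -400, 400),
                       lambdas = lam, lookahead_n = n)
    got <- lookahead_cost(p, origin, d, mm)
    want <- oracle_lookahead_cost(p, origin, d, mm)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("lookahead degenerate cases reduce to the one-step cost", {
  d <- generate_display("value", seed = 9)
  mm <- hand_model()
  p1 <- choice_params(beta = 1, w1 = 200, gamma = 1, w2 = 100)
  expect_equal(lookahead_cost(p1, "start", d, mm),
               step_cost(p1, "start", 0:14, d, mm))
  # all lambdas zero -> identical to one-step for any depth
  p5 <- choice_params(beta = 1, w1 = 200, gamma = 1, w2 = 100,
                      lambdas = rep(0, 4), lookahead_n = 5)
  expect_equal(unname(lookahead_cost(p5, "start", d, mm)),
               unname(step_cost(p5, "start", 0:14, d, mm)))
})

test_that("softmax probabilities are normalized, ordered and stable", {
  d <- generate_display("small_low", seed = 13)
  mm <- hand_model()

  # beta = 0 with 14 candidates -> uniform 1/14
  d1 <- mark_harvested(d, 6L)
  p <- choice_probabilities(choice_params(0), 6L, d1, mm)
  expect_equal(unname(p), rep(1 / 14, 14))

  # two candidates with costs 1 and 2 at beta 1 -> (0.7311, 0.2689)
  z <- exp(-1 * c(1, 2)); z <- z / sum(z)
  expect_equal(round(z, 4), c(0.7311, 0.2689)) # direct evaluation frozen

  pf <- choice_params(beta = 0.05, w1 = 500, gamma = 1, w2 = 300)
  pr <- choice_probabilities(pf, "start", d, mm)
  expect_equal(sum(pr), 1)
  C <- lookahead_cost(pf, "start", d, mm)
  expect_equal(order(-pr), order(C)) # inverse ordering to cost

  # huge beta -> min-cost candidate takes everything (max-subtraction works)
  pb <- choice_params(beta = 1e6, w1 = 500, gamma = 1, w2 = 300)
  prb <- choice_probabilities(pb, "start", d, mm)
  expect_equal(max(prb), 1)
  expect_equal(names(which.max(prb)), names(which.min(C)))

  # monotonicity: larger distance strictly lowers probability (w1 > 0)
  pd <- choice_params(beta = 0.1, w1 = 300, gamma = 1,
                      include_reward_rate = FALSE, include_size = FALSE)
  prd <- choice_probabilities(pd, "start", d, mm)
  dm <- distance_matrix(d)[16, 1:15]
  expect_equal(order(-prd), order(dm))

  d_all <- mark_harvested(d, 0:14)
  expect_error(choice_probabilities(pf, 0L, d_all, mm), "no legal candidates")
})

test_that("session log-likelihood matches hand computation and invariants", {
  sess <- small_session(trials_per_condition = 2L, seed = 5)

  # beta = 0: every scored choice contributes -log(remaining candidates)
  ll0 <- session_log_likelihood(choice_params(0), sess)
  want <- -sum(vapply(sess$trials, function(tr) {
    ks <- 2:min(nrow(tr$harvests), 8L)
    sum(log(16 - ks))
  }, numeric(1)))
  expect_equal(as.numeric(ll0), want)
  # a full trial of harvests 2..8 contributes -(log 14 + ... + log 8)
  expect_equal(-sum(log(14:8)), -16.66606, tolerance = 1e-5)

  # shift invariance: adding a constant to every candidate's size term
  # (via w2 with all sizes equal) leaves the likelihood unchanged
  sz <- generate_session(agent_spec("model", params = reference_params()),
                         conditions = "value", trials_per_condition = 3,
                         seed = 31)
  base <- choice_params(beta = 0.07, w1 = 400, gamma = 1, w2 = 0)
  shifted <- choice_params(beta = 0.07, w1 = 400, gamma = 1, w2 = 12345)
  expect_equal(as.numeric(session_log_likelihood(base, sz)),
               as.numeric(session_log_likelihood(shifted, sz)),
               tolerance = 1e-8)

  # continuity: small parameter perturbations move the likelihood smoothly
  p <- reference_params()
  ll <- as.numeric(session_log_likelihood(p, sess))
  for (dp in list(c(1e-6, 0, 0, 0), c(0, 1e-3, 0, 0), c(0, 0, 1e-6, 0),
                  c(0, 0, 0, 1e-3))) {
    p2 <- choice_params(p$beta + dp[1], p$w1 + dp[2], p$gamma + dp[3],
                        p$w2 + dp[4])
    expect_lt(abs(as.numeric(session_log_likelihood(p2, sess)) - ll), 0.5)
  }
})
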