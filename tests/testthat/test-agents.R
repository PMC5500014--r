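test_that("simulate_trial respects the clock and legality", {
  mm <- hand_model()
  d <- generate_display("small_high", seed = 2)

  # tiny budget -> no harvests
  tiny <- agent_spec("uniform", time_budget = 0.01, time_noise_sd = 0)
  s <- simulate_trial(tiny, d, mm)
  expect_equal(nrow(s$harvests), 0L)
  expect_equal(s$points, 0)

  # clock conservation and consistent bookkeeping
  set.seed(10)
  ag <- agent_spec("uniform", time_noise_sd = 0.08)
  for (r in 1:5) {
    s <- simulate_trial(ag, generate_display("value", seed = NULL), mm)
    expect_lte(sum(s$harvests$time), 3.25)
    expect_false(anyDuplicated(s$harvests$chosen) > 0)
    expect_equal(s$harvests$origin,
                 c(15L, s$harvests$chosen[-nrow(s$harvests)]))
  }

  # constrained model agent emits non-increasing values
  set.seed(11)
  dd <- generate_display("small_high", seed = NULL)
  cag <- agent_spec("model", params = reference_params(), constrained = TRUE)
  s <- simulate_trial(cag, dd, mm)
  got <- dd$targets$value[match(s$harvests$chosen, dd$targets$id)]
  expect_true(all(diff(got) <= 0))
})

test_that("uniform hand agent harvests roughly as many targets as observed", {
  # noiseless hand-like timing, 3.25 s budget: mean harvests within +-1 of 8.4
  sess <- generate_session(agent_spec("uniform", time_noise_sd = 0),
                           trials_per_condition = 12, seed = 19)
  nh <- vapply(sess$trials, function(tr) nrow(tr$harvests), integer(1))
  expect_gt(mean(nh), 7.4)
  expect_lt(mean(nh), 9.4)
})

test_that("planner choice matches the exhaustive oracle on small instances", {
  mm <- hand_model()
  set.seed(77)
  for (r in 1:8) {
    d <- generate_display(sample(c("value", "small_high"), 1), seed = NULL)
    d <- mark_harvested(d, sample(0:14, sample(7:11, 1)))
    rem <- runif(1, 0.4, 2.2)
    got <- optimal_planner_choice(d, mm, rem, depth = 5)
    want <- oracle_planner(d, mm, rem, depth = 5)
    if (length(want$seq) == 0) {
      expect_length(got$sequence, 0)
    } else {
      expect_equal(got$sequence, want$seq)
      expect_equal(got$points, want$pts)
      expect_equal(got$time, want$time, tolerance = 1e-10)
      expect_equal(got$rate, want$rate, tolerance = 1e-10)
    }
  }
})

test_that("planner edge cases: singleton, nearer-of-equal, infeasible", {
  mm <- hand_model()
  d <- zero_jitter_display("size", seed = 1)
  d1 <- mark_harvested(d, setdiff(0:14, 3L))
  pc <- optimal_planner_choice(d1, mm, 3, depth = 1)
  expect_equal(pc$sequence, 3L)
  dist <- distance_matrix(d1)[16, 4]
  expect_equal(pc$rate, 12 / (0.2 + dist), tolerance = 1e-10)

  # two same-size same-value targets: nearer one wins at depth 1
  t <- d$targets
  near <- t$id[which.min(distance_matrix(d)[16, 1:15])]
  far <- t$id[which.max(distance_matrix(d)[16, 1:15])]
  d2 <- mark_harvested(d, setdiff(0:14, c(near, far)))
  d2$targets$radius[] <- 0.008
  d2$targets$value[] <- 12
  pc2 <- optimal_planner_choice(d2, mm, 3.25, depth = 1)
  expect_equal(pc2$sequence, near)

  # nothing fits -> empty sentinel
  pc3 <- optimal_planner_choice(d, mm, 0.05, depth = 5)
  expect_length(pc3$sequence, 0)
  expect_true(is.na(pc3$rate))
})

test_that("generate_session builds the standard blocks reproducibly", {
  ag <- agent_spec("greedy", time_noise_sd = 0)
  s1 <- generate_session(ag, trials_per_condition = 2, seed = 6)
  expect_length(s1$trials, 8) # 4 free conditions
  expect_equal(unique(vapply(s1$trials, function(tr) tr$display$condition,
                             character(1))),
               c("size", "value", "small_high", "small_low"))
  cag <- agent_spec("greedy", time_noise_sd = 0, constrained = TRUE)
  s2 <- generate_session(cag, trials_per_condition = 2, seed = 6)
  expect_length(s2$trials, 6) # constrained drops the size condition
  expect_false("size" %in% vapply(s2$trials, function(tr)
    tr$display$condition, character(1)))

  s3 <- generate_session(ag, trials_per_condition = 2, seed = 6)
  expect_identical(s1, s3)
})

test_that("efficiency ratios are 1 against itself and below 1 for uniform", {
  ag <- agent_spec("uniform", time_noise_sd = 0)
  sess <- generate_session(ag, conditions = "value",
                           trials_per_condition = 15, seed = 8)
  pl <- planner_session(sess)
  self <- efficiency_ratios(pl, pl)
  expect_equal(self$points_ratio, 1.0)
  expect_equal(self$count_ratio, 1.0)
  eff <- efficiency_ratios(sess, pl)
  expect_lt(eff$points_ratio, 1.0)
})
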