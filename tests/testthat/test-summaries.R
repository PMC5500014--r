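test_that("selection diagnostics: chance curve and near-deterministic agent", {
  # chance level is exactly 1/(16-h) for h = 2..8
  sess <- small_session(trials_per_condition = 3L, seed = 51)
  di <- selection_diagnostics(sess, choice_params(0))
  expect_equal(di$chance, 1 / (16 - di$harvest))
  expect_equal(di$chance[di$harvest == 2], 1 / 14, tolerance = 1e-12)
  if (8 %in% di$harvest) expect_equal(di$chance[di$harvest == 8], 0.125)
  # beta = 0 diagnosis assigns uniform probability to the taken target
  expect_equal(di$mean_prob_taken, di$chance)

  # near-deterministic agent diagnosed with its own model: hits its top pick
  det <- choice_params(beta = 50, w1 = 500, gamma = 1, w2 = 300)
  dsess <- generate_session(agent_spec("model", params = det,
                                       time_noise_sd = 0),
                            conditions = "small_low",
                            trials_per_condition = 6, seed = 52)
  dd <- selection_diagnostics(dsess, det)
  expect_gt(sum(dd$top_hit_rate * dd$n_choices) / sum(dd$n_choices), 0.95)
  expect_lt(sum(dd$mean_rank * dd$n_choices) / sum(dd$n_choices), 1.1)
})

test_that("selection proportions sum to one and track a value-greedy agent", {
  # greedy-by-value agent: make value dominate the reward rate
  vg <- choice_params(beta = 100, include_distance = FALSE,
                      include_size = FALSE)
  mm <- movement_time_model("hand", slope = 0, intercept = 0.4)
  ag <- agent_spec("model", params = vg, time_noise_sd = 0,
                   time_budget = 3.3) # 8 harvests at 0.4 s each
  sess <- generate_session(ag, movement_model = mm, conditions = "value",
                           trials_per_condition = 4, seed = 61)
  sp <- selection_proportions(sess)
  sums <- tapply(sp$proportion, list(sp$condition, sp$harvest), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # harvests 2..5 take the remaining high-value targets, then mid tier
  hi25 <- sp$proportion[sp$tier == 15 & sp$harvest %in% 2:5]
  expect_true(all(hi25 == 1))
  expect_true(all(sp$proportion[sp$tier == 12 & sp$harvest %in% 7:8] == 1))

  # uniform agent, value condition: tier proportions track availability
  us <- generate_session(agent_spec("uniform"), conditions = "value",
                         trials_per_condition = 60, seed = 62)
  usp <- selection_proportions(us)
  h2 <- usp[usp$harvest == 2, ]
  expect_true(all(abs(h2$proportion - 1 / 3) < 0.12)) # 14 remaining, ~5 each
})

test_that("distance distribution peaks at grid spacing for adjacent moves", {
  # a strongly distance-averse agent on zero-jitter displays moves between
  # adjacent targets: modal bin at 0.06 m
  near <- choice_params(beta = 5, w1 = 100, gamma = 1,
                        include_reward_rate = FALSE, include_size = FALSE)
  ag <- agent_spec("model", params = near, time_noise_sd = 0)
  sess <- generate_session(ag, conditions = "size", trials_per_condition = 6,
                           seed = 71, jitter = 0)
  dd <- distance_distribution(sess)
  expect_equal(sum(dd$freq), 1)
  expect_true(attr(dd, "mode") > 0.045 && attr(dd, "mode") < 0.075)

  # no two-harvest trials -> empty histogram
  tiny <- generate_session(agent_spec("uniform", time_budget = 0.3,
                                      time_noise_sd = 0),
                           conditions = "size", trials_per_condition = 2,
                           seed = 72)
  expect_equal(nrow(distance_distribution(tiny)), 0)

  # uniform agent has a heavier tail than a greedy-nearest agent
  us <- generate_session(agent_spec("uniform", time_noise_sd = 0),
                         conditions = "size", trials_per_condition = 10,
                         seed = 73)
  ns <- generate_session(ag, conditions = "size", trials_per_condition = 10,
                         seed = 73)
  mean_d <- function(s) {
    dd <- distance_distribution(s)
    sum((dd$bin_lo + 0.0075) * dd$freq)
  }
  expect_gt(mean_d(us), mean_d(ns))
})

test_that("path ranking agrees with brute-force enumeration", {
  # five collinear, equally spaced high-value targets: the monotone sweep
  # from the start end is the unique shortest path
  mk_trial <- function(order_ids) {
    targets <- data.frame(
      id = 0:14,
      x = c(rep(0, 5), rep(0.3, 10)),
      y = c(0.06 * (1:5), 0.06 + 0.01 * (0:9)),
      radius = 0.008,
      value = c(rep(15, 5), rep(12, 5), rep(10, 5)),
      harvested = FALSE)
    disp <- seqforage:::new_display(targets, "value", 1L)
    h <- data.frame(trial_id = 1L, harvest_index = 1:5, chosen = order_ids,
                    origin = c(15L, order_ids[-5]), time = 0.3)
    list(display = disp, harvests = h)
  }
  sweep_sess <- forage_session(list(mk_trial(0:4)), "hand",
                               constrained = TRUE)
  pr <- path_ranking(sweep_sess)
  expect_equal(ncol(pr$candidate_lengths), 120)
  expect_equal(pr$trials$rank, 1L)
  expect_equal(pr$trials$actual_length, 0.06 + 4 * 0.06, tolerance = 1e-12)
  expect_equal(pr$prop_rank1, 1.0)

  # a scrambled order ranks exactly where the oracle enumeration puts it
  scr_sess <- forage_session(list(mk_trial(c(2L, 0L, 4L, 1L, 3L))), "hand",
                             constrained = TRUE)
  pr2 <- path_ranking(scr_sess)
  perms <- seqforage:::permutations(5L)
  ys <- 0.06 * (1:5)
  plen <- function(ord) ys[ord[1]] + sum(abs(diff(ys[ord])))
  lens <- apply(perms, 1, plen)
  actual <- plen(c(3, 1, 5, 2, 4))
  expect_equal(pr2$trials$rank, sum(lens < actual - 1e-12) + 1L)
  expect_equal(sort(lens), unname(pr2$candidate_lengths[1, ]),
               tolerance = 1e-12)

  # trials without the five high-value harvests first are excluded
  bad <- mk_trial(c(0L, 1L, 2L, 3L, 5L))
  mix <- forage_session(list(mk_trial(0:4), bad), "hand", constrained = TRUE)
  pr3 <- path_ranking(mix)
  expect_equal(pr3$n_excluded, 1L)
  expect_equal(nrow(pr3$trials), 1L)

  # start leg can be excluded
  pr4 <- path_ranking(sweep_sess, include_start_leg = FALSE)
  expect_equal(pr4$trials$actual_length, 4 * 0.06, tolerance = 1e-12)
})
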