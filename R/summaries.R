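# Diagnostic summaries: model-vs-data selection probabilities and ranks,
# tier selection proportions over harvests, movement-distance distributions,
# and shortest-path ranking for the constrained task.

#' Selection diagnostics of a fitted model on a session
#'
#' Recomputes the model's choice probabilities at every scored choice
#' (harvests 2-8) and aggregates, per harvest index: the proportion of
#' choices where the chooser took the model's highest-probability target,
#' the mean model probability of the taken target, the mean gap to the top
#' probability, the mean rank of the taken target (1 = most probable;
#' probability ties broken by lowest target id), and the chance level
#' `1/(16 - h)`.
#'
#' @param session A `forage_session`.
#' @param fitted A `forage_fit` or `choice_params` to diagnose with.
#' @return Data frame with one row per harvest index 2-8: `harvest`,
#'   `n_choices`, `top_hit_rate`, `mean_prob_taken`, `mean_gap`, `mean_rank`,
#'   `chance`.
#' @export
selection_diagnostics <- function(session, fitted) {
  params <- if (inherits(fitted, "forage_fit")) fitted$params else fitted
  stopifnot(inherits(params, "choice_params"))
  rows <- list()
  for (tr in session$trials) {
    h <- tr$harvests
    if (nrow(h) < 2L) next
    disp <- tr$display
    disp$targets$harvested <- FALSE
    disp <- mark_harvested(disp, h$chosen[1L])
    for (k in 2:min(nrow(h), 8L)) {
      p <- choice_probabilities(params, h$chosen[k - 1L], disp,
                                session$movement_model,
                                constrained = session$constrained)
      ids <- as.integer(names(p))
      ord <- order(-p, ids) # descending probability, ties to lowest id
      taken <- match(h$chosen[k], ids)
      rows[[length(rows) + 1L]] <- data.frame(
        harvest = k,
        hit = ids[ord[1L]] == h$chosen[k],
        prob_taken = p[[taken]],
        gap = p[[ord[1L]]] - p[[taken]],
        rank = match(taken, ord),
        n_avail = length(ids))
      disp <- mark_harvested(disp, h$chosen[k])
    }
  }
  if (length(rows) == 0L) stopf("session has no scored choices")
  d <- do.call(rbind, rows)
  agg <- lapply(split(d, d$harvest), function(g) {
    data.frame(harvest = g$harvest[1L], n_choices = nrow(g),
               top_hit_rate = mean(g$hit),
               mean_prob_taken = mean(g$prob_taken),
               mean_gap = mean(g$gap), mean_rank = mean(g$rank),
               chance = 1 / (16 - g$harvest[1L]))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Selection proportions by target tier over harvests
#'
#' For each condition and harvest index 2-8, the proportion of chosen
#' targets falling in each value (or, for the size condition, size) tier.
#' Proportions sum to 1 across tiers within a harvest. Model-predicted
#' curves are obtained by calling this on Monte-Carlo rollout sessions
#' ([rollout_session()]).
#'
#' @param session A `forage_session`.
#' @param tier_by `"value"` or `"radius"`; default uses value except for the
#'   size condition, which tiers by radius.
#' @return Data frame: `condition`, `harvest`, `tier`, `n`, `proportion`.
#' @export
selection_proportions <- function(session, tier_by = NULL) {
  rows <- list()
  for (tr in session$trials) {
    h <- tr$harvests
    if (nrow(h) < 2L) next
    cond <- tr$display$condition
    by <- tier_by %||% (if (cond == "size") "radius" else "value")
    tiers <- tr$display$targets[[by]]
    for (k in 2:min(nrow(h), 8L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, harvest = k, tier = tiers[h$chosen[k] + 1L])
    }
  }
  if (length(rows) == 0L) stopf("session has no scored choices")
  d <- do.call(rbind, rows)
  tab <- as.data.frame(table(condition = d$condition, harvest = d$harvest,
                             tier = d$tier), stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tab$harvest <- as.integer(tab$harvest)
  tab$tier <- as.numeric(tab$tier)
  tot <- stats::ave(tab$n, tab$condition, tab$harvest, FUN = sum)
  tab$proportion <- ifelse(tot > 0, tab$n / tot, NA_real_)
  tab[order(tab$condition, tab$harvest, tab$tier), , drop = FALSE]
}

#' Monte-Carlo rollout sessions of a model on existing displays
#'
#' Simulates a model agent on the same displays as `session` (fresh
#' harvested flags), `n_rollouts` times, concatenating the rollouts into one
#' session. Used to build model-predicted selection-proportion and distance
#' curves.
#'
#' @param params A `choice_params` (or `forage_fit`).
#' @param session The reference `forage_session` providing displays, timing
#'   model and constraint flag.
#' @param n_rollouts Rollouts per trial (default 25).
#' @param seed Integer seed.
#' @return A `forage_session` of simulated trials.
#' @export
rollout_session <- function(params, session, n_rollouts = 25L, seed = 1L) {
  if (inherits(params, "forage_fit")) params <- params$params
  agent <- agent_spec("model", params = params, effector = session$effector,
                      constrained = session$constrained)
  trials <- with_seed(seed, {
    out <- list()
    for (r in seq_len(n_rollouts)) {
      for (tr in session$trials) {
        disp <- tr$display
        disp$targets$harvested <- FALSE
        sim <- simulate_trial(agent, disp, session$movement_model)
        out[[length(out) + 1L]] <- list(display = disp,
                                        harvests = sim$harvests,
                                        points = sim$points)
      }
    }
    out
  })
  forage_session(trials, effector = session$effector,
                 movement_model = session$movement_model,
                 constrained = session$constrained,
                 agent_kind = "model_rollout", seed = seed)
}

#' Distribution of successive harvest-to-harvest distances
#'
#' Histogram of center-to-center distances between consecutively harvested
#' targets (the start-to-first leg is excluded).
#'
#' @param session A `forage_session`.
#' @param bin_width Bin width in metres (default 0.015; first edge at 0).
#' @return Data frame with `bin_lo`, `bin_hi`, `count`, `freq`; the modal
#'   bin's midpoint is attached as attribute `"mode"`. Empty when no trial
#'   has two harvests.
#' @export
distance_distribution <- function(session, bin_width = 0.015) {
  dists <- numeric(0)
  for (tr in session$trials) {
    h <- tr$harvests
    if (nrow(h) < 2L) next
    xy <- as.matrix(tr$display$targets[, c("x", "y")])
    a <- xy[h$chosen[-nrow(h)] + 1L, , drop = FALSE]
    b <- xy[h$chosen[-1L] + 1L, , drop = FALSE]
    dists <- c(dists, sqrt(rowSums((a - b)^2)))
  }
  if (length(dists) == 0L) {
    out <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0), freq = numeric(0))
    attr(out, "mode") <- NA_real_
    return(out)
  }
  edges <- seq(0, (floor(max(dists) / bin_width) + 1L) * bin_width,
               by = bin_width)
  cnt <- tabulate(findInterval(dists, edges, rightmost.closed = TRUE),
                  nbins = length(edges) - 1L)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                    count = cnt, freq = cnt / sum(cnt))
  attr(out, "mode") <- out$bin_lo[which.max(cnt)] + bin_width / 2
  out
}

# All permutations of 1..n (n small), one per row.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Path ranking for the constrained task
#'
#' For each constrained trial whose first five harvests are the five
#' high-value targets, enumerates all 120 orderings of those targets, sums
#' the center-to-center path length of each (optionally including the
#' start-to-first leg, the default), and ranks the actually chosen order
#' (rank 1 = shortest; ties share the lower rank).
#'
#' @param constrained_session A constrained `forage_session`.
#' @param include_start_leg Include the start-position-to-first-target leg
#'   in every path length (default `TRUE`).
#' @return A list of class `path_ranking`: `trials` (data frame `trial_id`,
#'   `actual_length`, `rank`), `candidate_lengths` (120-column matrix, one
#'   row per scored trial, each row sorted ascending), `n_excluded`,
#'   `prop_rank1`, `prop_rank_le5`, `mean_length_by_rank`.
#' @export
path_ranking <- function(constrained_session, include_start_leg = TRUE) {
  stopifnot(inherits(constrained_session, "forage_session"))
  perms <- permutations(5L)
  rows <- list(); cand_all <- list(); excluded <- 0L
  for (tr in constrained_session$trials) {
    h <- tr$harvests
    tg <- tr$display$targets
    hi <- tg$id[tg$value == max(tg$value)]
    if (length(hi) != 5L || nrow(h) < 5L ||
        !setequal(h$chosen[1:5], hi)) {
      excluded <- excluded + 1L
      next
    }
    xy <- rbind(as.matrix(tg[match(hi, tg$id), c("x", "y")]),
                matrix(tr$display$start, nrow = 1))
    plen <- function(ord) { # ord indexes into hi (1..5)
      pts <- xy[ord, , drop = FALSE]
      len <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                               pts[-5, , drop = FALSE])^2)))
      if (include_start_leg) len <- len + sqrt(sum((xy[6, ] - pts[1, ])^2))
      len
    }
    cand <- apply(perms, 1L, plen)
    actual <- plen(match(h$chosen[1:5], hi))
    rank <- sum(cand < actual - 1e-12) + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = tr$display$trial_id, actual_length = actual, rank = rank)
    cand_all[[length(cand_all) + 1L]] <- sort(cand)
  }
  if (length(rows) == 0L) stopf("no trial has all five high-value targets harvested first")
  trials <- do.call(rbind, rows)
  cl <- do.call(rbind, cand_all)
  structure(
    list(trials = trials, candidate_lengths = cl, n_excluded = excluded,
         prop_rank1 = mean(trials$rank == 1L),
         prop_rank_le5 = mean(trials$rank <= 5L),
         mean_length_by_rank = colMeans(cl)),
    class = "path_ranking"
  )
}

#' @export
print.path_ranking <- function(x, ...) {
  cat(sprintf(
    "<path_ranking> %d trials (%d excluded): rank 1 on %.1f%%, rank <= 5 on %.1f%%\n",
    nrow(x$trials), x$n_excluded, 100 * x$prop_rank1, 100 * x$prop_rank_le5))
  invisible(x)
}
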