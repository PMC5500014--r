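# Maximum-likelihood fitting of the choice model per session, BIC model
# comparison across submodels and look-ahead depths, and normalized
# look-ahead weights.

SUBMODELS <- c("full", "no_reward_rate", "no_distance", "no_size")

# Free-parameter layout for a submodel at a given depth. beta and gamma are
# optimized on the log scale; w1, w2 and the lambdas are unconstrained.
# Removing the reward-rate term leaves beta unidentified (only beta*w1 and
# beta*w2 enter the likelihood), so beta is fixed at 1 there; each removed
# component reduces k accordingly (no_distance drops w1 and gamma).
param_layout <- function(submodel, lookahead_n) {
  submodel <- match.arg(submodel, SUBMODELS)
  nl <- lookahead_n - 1L
  free <- c(
    if (submodel != "no_reward_rate") "log_beta",
    if (submodel != "no_distance") c("w1", "log_gamma"),
    if (submodel != "no_size") "w2",
    if (nl > 0L) paste0("lambda", seq_len(nl))
  )
  list(submodel = submodel, lookahead_n = lookahead_n, free = free,
       k = length(free))
}

unpack_params <- function(theta, layout) {
  g <- function(nm, default) {
    i <- match(nm, layout$free)
    if (is.na(i)) default else theta[i]
  }
  nl <- layout$lookahead_n - 1L
  lambdas <- if (nl > 0L) {
    vapply(paste0("lambda", seq_len(nl)), function(nm) g(nm, 0), numeric(1))
  } else numeric(0)
  choice_params(
    beta = exp(g("log_beta", 0)), # fixed at exp(0)=1 for no_reward_rate
    w1 = g("w1", 0),
    gamma = exp(g("log_gamma", 0)),
    w2 = g("w2", 0),
    lambdas = unname(lambdas),
    lookahead_n = layout$lookahead_n,
    include_reward_rate = layout$submodel != "no_reward_rate",
    include_distance = layout$submodel != "no_distance",
    include_size = layout$submodel != "no_size"
  )
}

# Random restart starting points: log-uniform for beta and gamma, uniform
# over documented ranges for w1, w2 and the lambdas.
draw_start <- function(layout) {
  vapply(layout$free, function(nm) {
    if (startsWith(nm, "lambda")) return(runif(1, 0, 1))
    switch(nm,
      log_beta = runif(1, log(0.005), log(0.5)),
      log_gamma = runif(1, log(0.3), log(3)),
      w1 = runif(1, 0, 1000),
      w2 = runif(1, -500, 500))
  }, numeric(1))
}

#' Bayesian Information Criterion
#'
#' `-2 * log_likelihood + k * log(N)`; lower is better.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param k Number of free parameters (>= 0).
#' @param N Number of scored choices (>= 1).
#' @return The BIC (scalar).
#' @export
bic <- function(log_likelihood, k, N) {
  stopifnot(N >= 1, k >= 0)
  -2 * log_likelihood + k * log(N)
}

#' Fit the choice model to a session by maximum likelihood
#'
#' Derivative-free Nelder-Mead simplex search with multiple random restarts.
#' beta and gamma are optimized through log transforms (kept positive); w1,
#' w2 and the look-ahead discount weights are unconstrained. The best
#' restart is returned.
#'
#' @param session A `forage_session` with at least `min_choices` scored
#'   choices (harvests 2-8 pooled over all trials and conditions).
#' @param lookahead_n Look-ahead depth of the fitted model (1-5).
#' @param submodel `"full"`, or one component removed: `"no_reward_rate"`,
#'   `"no_distance"` (drops both `w1` and `gamma`), `"no_size"`.
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed controlling the restart draws (fit is fully
#'   deterministic given `seed`).
#' @param max_eval Maximum function evaluations per restart.
#' @param reltol Relative convergence tolerance of the simplex.
#' @param min_choices Minimum scored choices required (default 50).
#' @param k_override Optional integer overriding the free-parameter count
#'   used in the BIC (sensitivity checks only).
#' @return An object of class `forage_fit`: fitted `params`,
#'   `log_likelihood`, `k`, `n_choices`, `bic`, `n_restarts`, `converged`,
#'   `seed`, and the per-restart log-likelihoods.
#' @export
fit_session <- function(session, lookahead_n = 1L, submodel = "full",
                        n_restarts = 10L, seed = 1L, max_eval = 5000L,
                        reltol = 1e-6, min_choices = 50L, k_override = NULL) {
  ctx <- session_context(session)
  if (ctx$n < min_choices)
    stopf("session has %d scored choices; >= %d required", ctx$n, min_choices)
  layout <- param_layout(submodel, as.integer(lookahead_n))

  negll <- function(theta) {
    p <- unpack_params(theta, layout)
    v <- tryCatch(context_loglik(ctx, p), error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }

  runs <- with_seed(seed, {
    starts <- replicate(n_restarts, draw_start(layout), simplify = FALSE)
    lapply(starts, function(th0) {
      tryCatch(
        optim(th0, negll, method = "Nelder-Mead",
              control = list(maxit = max_eval, reltol = reltol)),
        error = function(e) NULL)
    })
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L) stopf("all %d restarts failed to evaluate", n_restarts)
  lls <- vapply(runs, function(r) -r$value, numeric(1))
  best <- runs[[which.max(lls)]]
  # polish: re-running the simplex from the incumbent rebuilds the simplex
  # and escapes premature stops along nearly flat directions
  for (round in 1:3) {
    nxt <- optim(best$par, negll, method = "Nelder-Mead",
                 control = list(maxit = max_eval, reltol = reltol))
    if (best$value - nxt$value < 1e-6) { best <- nxt; break }
    best <- nxt
  }
  k <- if (is.null(k_override)) layout$k else as.integer(k_override)
  structure(
    list(params = unpack_params(best$par, layout),
         log_likelihood = -best$value,
         k = k, n_choices = ctx$n,
         bic = bic(-best$value, k, ctx$n),
         n_restarts = n_restarts,
         converged = best$convergence == 0,
         seed = seed,
         submodel = layout$submodel,
         restart_log_likelihoods = lls),
    class = "forage_fit"
  )
}

#' @export
print.forage_fit <- function(x, ...) {
  cat(sprintf(
    "<forage_fit> %s, n=%d look-ahead: logL=%.2f, k=%d, N=%d, BIC=%.2f\n",
    x$submodel, x$params$lookahead_n, x$log_likelihood, x$k, x$n_choices,
    x$bic))
  print(x$params)
  invisible(x)
}

#' Compare the full model against its single-component submodels
#'
#' Fits the full model and the three submodels (reward rate, distance, or
#' size removed) at a fixed look-ahead depth, and reports the BIC difference
#' of each row relative to the full model.
#'
#' @inheritParams fit_session
#' @param ... Passed to [fit_session()].
#' @return A `comparison_table`: data frame with columns `lookahead_n`,
#'   `submodel`, `log_likelihood`, `k`, `n_choices`, `bic`, `delta_bic`,
#'   `converged`; the fits are attached as attribute `"fits"`. Rows whose fit
#'   failed carry `NA`s and `converged = FALSE`.
#' @export
compare_submodels <- function(session, lookahead_n = 1L, seed = 1L, ...) {
  fits <- lapply(seq_along(SUBMODELS), function(i) {
    tryCatch(
      fit_session(session, lookahead_n = lookahead_n, submodel = SUBMODELS[i],
                  seed = seed + i - 1L, ...),
      error = function(e) NULL)
  })
  names(fits) <- SUBMODELS
  tab <- comparison_rows(fits, lookahead_n)
  ref <- tab$bic[tab$submodel == "full"]
  tab$delta_bic <- tab$bic - ref
  structure(tab, fits = fits, class = c("comparison_table", "data.frame"))
}

#' Compare look-ahead depths of the full model
#'
#' Fits the full model at each depth in `n_range` and reports BICs relative
#' to the 1-look-ahead value (the reference row has `delta_bic = 0`); the
#' arg-min depth is flagged as best.
#'
#' @inheritParams fit_session
#' @param n_range Integer vector of depths to fit (default `1:5`).
#' @param ... Passed to [fit_session()].
#' @return A `comparison_table` (see [compare_submodels()]) with an extra
#'   logical column `best`; attribute `"best_n"` holds the best depth.
#' @export
compare_lookaheads <- function(session, n_range = 1:5, seed = 1L, ...) {
  n_range <- sort(unique(as.integer(n_range)))
  fits <- lapply(seq_along(n_range), function(i) {
    tryCatch(
      fit_session(session, lookahead_n = n_range[i], submodel = "full",
                  seed = seed + 100L * i, ...),
      error = function(e) NULL)
  })
  names(fits) <- paste0("n", n_range)
  tab <- comparison_rows(fits, n_range)
  tab$submodel <- "full"
  ref <- if (1L %in% n_range) tab$bic[tab$lookahead_n == 1L][1] else
    tab$bic[1]
  tab$delta_bic <- tab$bic - ref
  tab$best <- !is.na(tab$bic) & tab$bic == min(tab$bic, na.rm = TRUE)
  structure(tab, fits = fits, best_n = tab$lookahead_n[which(tab$best)[1]],
            class = c("comparison_table", "data.frame"))
}

comparison_rows <- function(fits, lookahead_n) {
  grab <- function(f, field) if (is.null(f)) NA_real_ else f[[field]]
  data.frame(
    lookahead_n = rep_len(lookahead_n, length(fits)),
    submodel = names(fits),
    log_likelihood = vapply(fits, grab, numeric(1), "log_likelihood"),
    k = vapply(fits, grab, numeric(1), "k"),
    n_choices = vapply(fits, grab, numeric(1), "n_choices"),
    bic = vapply(fits, grab, numeric(1), "bic"),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    row.names = NULL
  )
}

#' Normalized look-ahead weights
#'
#' The weight vector `(1, lambda_1, ..., lambda_{n-1})` of a fitted model,
#' normalized to sum to one.
#'
#' @param fit A `forage_fit` (or a `choice_params`).
#' @return Numeric vector of length `lookahead_n` summing to 1.
#' @export
normalized_lookahead_weights <- function(fit) {
  p <- if (inherits(fit, "forage_fit")) fit$params else fit
  stopifnot(inherits(p, "choice_params"))
  w <- c(1, p$lambdas)
  if (sum(w) <= 0) stopf("degenerate fit: look-ahead weights sum to <= 0")
  w / sum(w)
}
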