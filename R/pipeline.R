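# Configuration-driven pipeline: simulate -> fit -> compare -> summarize,
# with a manifest recording inputs, seeds, package version and content
# hashes of every written file. A thin command-line wrapper lives in
# inst/cli/seqforage.R.

read_config <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config), length(config) == 1L, file.exists(config))
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("yaml package unavailable; use a JSON config")
    yaml::read_yaml(config)
  } else {
    jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
}

config_agent <- function(cfg, params) {
  agent_spec(
    kind = cfg$kind %||% "model",
    params = params,
    effector = cfg$effector %||% "hand",
    time_budget = cfg$time_budget %||% 3.25,
    time_noise_sd = cfg$time_noise_sd %||% 0.08,
    constrained = isTRUE(cfg$constrained))
}

config_params <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  choice_params(
    beta = cfg$beta %||% 0.05, w1 = cfg$w1 %||% 0,
    gamma = cfg$gamma %||% 1, w2 = cfg$w2 %||% 0,
    lambdas = cfg$lambdas %||% numeric(0),
    lookahead_n = cfg$lookahead_n %||% 1L)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in order: `simulate` (synthetic session
#' from a configured agent), `fit` (maximum-likelihood fit), `compare`
#' (submodel and look-ahead BIC grids), `summarize` (selection diagnostics,
#' tier proportions, distance histogram, and path ranking for constrained
#' sessions). Every stage seed derives deterministically from the global
#' seed, so a rerun with the same config reproduces identical artifacts.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent list.
#'   Top-level fields: `seed`, `out_dir`, `stages` (character vector), and
#'   per-stage blocks `agent`, `params`, `simulate`, `fit`, `compare`.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return The manifest (list), invisibly; written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$out_dir %||% "seqforage-out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages %||% c("simulate", "fit", "compare", "summarize")
  written <- character(0)
  note <- function(path) written <<- c(written, path)

  session <- NULL
  if ("simulate" %in% stages) {
    sim <- cfg$simulate %||% list()
    params <- config_params(cfg$params)
    agent <- config_agent(cfg$agent %||% list(), params)
    session <- generate_session(
      agent, trials_per_condition = sim$trials_per_condition %||% 50L,
      conditions = sim$conditions,
      seed = derive_seed(seed, "simulate"))
    p <- file.path(out_dir, "session.jsonl")
    write_session(session, p)
    note(p)
  } else if (!is.null(cfg$session_file)) {
    session <- read_session(cfg$session_file)
  }

  fit <- NULL
  if ("fit" %in% stages) {
    if (is.null(session)) stopf("fit stage requires a session")
    fc <- cfg$fit %||% list()
    fit <- fit_session(
      session, lookahead_n = fc$lookahead_n %||% 1L,
      submodel = fc$submodel %||% "full",
      n_restarts = fc$n_restarts %||% 10L,
      max_eval = fc$max_eval %||% 5000L,
      seed = derive_seed(seed, "fit"))
    p <- file.path(out_dir, "fit.json")
    jsonlite::write_json(
      list(submodel = fit$submodel, log_likelihood = fit$log_likelihood,
           k = fit$k, n_choices = fit$n_choices, bic = fit$bic,
           converged = fit$converged, seed = fit$seed,
           params = fit$params[c("beta", "w1", "gamma", "w2", "lambdas",
                                 "lookahead_n")]),
      p, auto_unbox = TRUE, digits = NA)
    note(p)
  }

  if ("compare" %in% stages) {
    if (is.null(session)) stopf("compare stage requires a session")
    cc <- cfg$compare %||% list()
    sub <- compare_submodels(
      session, lookahead_n = cc$lookahead_n %||% 1L,
      n_restarts = cc$n_restarts %||% 10L,
      max_eval = cc$max_eval %||% 5000L,
      seed = derive_seed(seed, "compare_sub"))
    p1 <- file.path(out_dir, "submodel_comparison.csv")
    write.csv(as.data.frame(sub), p1, row.names = FALSE)
    note(p1)
    la <- compare_lookaheads(
      session, n_range = cc$n_range %||% 1:3,
      n_restarts = cc$n_restarts %||% 10L,
      max_eval = cc$max_eval %||% 5000L,
      seed = derive_seed(seed, "compare_la"))
    p2 <- file.path(out_dir, "lookahead_comparison.csv")
    write.csv(as.data.frame(la), p2, row.names = FALSE)
    note(p2)
  }

  if ("summarize" %in% stages) {
    if (is.null(session)) stopf("summarize stage requires a session")
    diag_params <- if (!is.null(fit)) fit$params else config_params(cfg$params)
    if (!is.null(diag_params)) {
      p <- file.path(out_dir, "selection_diagnostics.csv")
      write.csv(selection_diagnostics(session, diag_params), p,
                row.names = FALSE)
      note(p)
    }
    p <- file.path(out_dir, "selection_proportions.csv")
    write.csv(selection_proportions(session), p, row.names = FALSE)
    note(p)
    p <- file.path(out_dir, "distance_distribution.csv")
    write.csv(distance_distribution(session), p, row.names = FALSE)
    note(p)
    if (isTRUE(session$constrained)) {
      pr <- path_ranking(session)
      p <- file.path(out_dir, "path_ranking.csv")
      write.csv(pr$trials, p, row.names = FALSE)
      note(p)
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("seqforage")),
    seed = seed, stages = stages,
    files = lapply(setNames(written, basename(written)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
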