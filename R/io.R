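# Serialization: sessions as JSON lines (one header line plus one trial per
# line) or as a displays/harvests CSV pair. Coordinates are stored in
# millimetres for readability and converted to metres on read, driven by a
# units flag in the header/table (legacy metre-unit files read unchanged).

MM <- 1000

session_header <- function(session) {
  list(schema = "seqforage-session", schema_version = 1L, units = "mm",
       effector = session$effector, constrained = session$constrained,
       agent_kind = session$agent_kind, seed = session$seed,
       movement_model = list(
         effector = session$movement_model$effector,
         slope = as.list(session$movement_model$slope),
         intercept = as.list(session$movement_model$intercept),
         sigma = as.list(session$movement_model$sigma)))
}

display_to_list <- function(display, scale) {
  t <- display$targets
  list(trial_id = display$trial_id, condition = display$condition,
       start_x = display$start[1] * scale, start_y = display$start[2] * scale,
       targets = data.frame(id = t$id, x = t$x * scale, y = t$y * scale,
                            radius = t$radius * scale, value = t$value))
}

#' Write a session to disk
#'
#' @param session A `forage_session`.
#' @param path Output path. For `"jsonl"` a single file; for `"csv-pair"`
#'   the stem for `<path>_displays.csv` and `<path>_harvests.csv`.
#' @param format `"jsonl"` or `"csv-pair"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = c("jsonl", "csv-pair")) {
  format <- match.arg(format)
  stopifnot(inherits(session, "forage_session"))
  if (format == "jsonl") {
    lines <- c(
      jsonlite::toJSON(session_header(session), auto_unbox = TRUE, digits = NA),
      vapply(session$trials, function(tr) {
        obj <- display_to_list(tr$display, MM)
        obj$harvests <- tr$harvests
        as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
      }, character(1)))
    writeLines(lines, path)
  } else {
    disp <- do.call(rbind, lapply(session$trials, function(tr) {
      t <- tr$display$targets
      data.frame(trial_id = tr$display$trial_id,
                 condition = tr$display$condition, units = "mm",
                 target_id = t$id, x = t$x * MM, y = t$y * MM,
                 radius = t$radius * MM, value = t$value)
    }))
    harv <- do.call(rbind, lapply(session$trials, function(tr) tr$harvests))
    meta <- data.frame(trial_id = NA_integer_, condition = "#meta",
                       units = "mm", target_id = NA_integer_,
                       x = NA_real_, y = NA_real_, radius = NA_real_,
                       value = NA_real_)
    write.csv(rbind(meta[0, ], disp), paste0(path, "_displays.csv"),
              row.names = FALSE)
    write.csv(harv, paste0(path, "_harvests.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a session from disk
#'
#' Validates the schema (exactly 15 targets per trial, known conditions) and
#' converts millimetre units to metres according to the units flag.
#'
#' @param path Path written by [write_session()] (for `"csv-pair"`, the stem).
#' @param format `"jsonl"` or `"csv-pair"`.
#' @return A `forage_session`.
#' @export
read_session <- function(path, format = c("jsonl", "csv-pair")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- readLines(path)
    hdr <- jsonlite::fromJSON(lines[1])
    if (!identical(hdr$schema, "seqforage-session"))
      stopf("%s: not a seqforage-session file", path)
    scale <- if (identical(hdr$units, "mm")) 1 / MM else 1
    mm <- movement_time_model(hdr$movement_model$effector,
                              unlist(hdr$movement_model$slope),
                              unlist(hdr$movement_model$intercept),
                              unlist(hdr$movement_model$sigma))
    trials <- lapply(seq_along(lines)[-1], function(i) {
      obj <- jsonlite::fromJSON(lines[i])
      t <- obj$targets
      if (is.null(t) || nrow(t) != N_TARGETS)
        stopf("line %d (trial %s): expected 15 targets, found %d",
              i, obj$trial_id %||% "?", NROW(t))
      targets <- data.frame(id = as.integer(t$id), x = t$x * scale,
                            y = t$y * scale, radius = t$radius * scale,
                            value = t$value, harvested = FALSE)
      h <- obj$harvests
      harvests <- if (is.null(h) || NROW(h) == 0L) {
        data.frame(trial_id = integer(0), harvest_index = integer(0),
                   chosen = integer(0), origin = integer(0),
                   time = numeric(0))
      } else {
        data.frame(trial_id = as.integer(h$trial_id),
                   harvest_index = as.integer(h$harvest_index),
                   chosen = as.integer(h$chosen),
                   origin = as.integer(h$origin), time = h$time)
      }
      disp <- new_display(targets, obj$condition, obj$trial_id)
      list(display = disp, harvests = harvests, points = sum_points(
        list(display = disp, harvests = harvests)))
    })
    forage_session(trials, effector = hdr$effector, movement_model = mm,
                   constrained = isTRUE(hdr$constrained),
                   agent_kind = hdr$agent_kind %||% NA_character_,
                   seed = hdr$seed %||% NA_integer_)
  } else {
    disp <- read.csv(paste0(path, "_displays.csv"))
    harv <- read.csv(paste0(path, "_harvests.csv"))
    scale <- if (all(disp$units == "mm")) 1 / MM else 1
    trials <- lapply(split(disp, disp$trial_id), function(d) {
      if (nrow(d) != N_TARGETS)
        stopf("trial %d: expected 15 targets, found %d",
              d$trial_id[1], nrow(d))
      targets <- data.frame(id = as.integer(d$target_id), x = d$x * scale,
                            y = d$y * scale, radius = d$radius * scale,
                            value = d$value, harvested = FALSE)
      h <- harv[harv$trial_id == d$trial_id[1], , drop = FALSE]
      rownames(h) <- NULL
      display <- new_display(targets[order(targets$id), ],
                             d$condition[1], d$trial_id[1])
      list(display = display, harvests = h,
           points = sum_points(list(display = display, harvests = h)))
    })
    trials <- trials[order(vapply(trials, function(tr) tr$display$trial_id,
                                  integer(1)))]
    names(trials) <- NULL
    forage_session(trials, effector = "hand")
  }
}

#' Serialize a movement-time model to JSON
#'
#' Coefficients are keyed by effector and radius tier in millimetres.
#'
#' @param model A `movement_time_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movement_model <- function(model, path) {
  stopifnot(inherits(model, "movement_time_model"))
  jsonlite::write_json(
    list(effector = model$effector, slope = as.list(model$slope),
         intercept = as.list(model$intercept), sigma = as.list(model$sigma)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movement_model
#' @export
read_movement_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  movement_time_model(obj$effector, unlist(obj$slope), unlist(obj$intercept),
                      unlist(obj$sigma))
}
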