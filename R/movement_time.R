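# Movement-time model: inter-harvest duration is close to linear in the
# distance moved, with coefficients that may differ across target sizes and
# effectors. An ordinary least-squares line is fitted per radius tier and
# used to predict the time t_ij of any candidate movement.

#' Construct a movement-time model
#'
#' Holds one (slope, intercept) pair per radius tier (5, 8, 11 mm) for a
#' given effector. Scalars are recycled across tiers; named vectors (names
#' `"5"`, `"8"`, `"11"`) set tiers individually.
#'
#' @param effector `"hand"` or `"eye"`.
#' @param slope Slope(s) in s/m.
#' @param intercept Intercept(s) in s.
#' @param sigma Residual standard deviation(s) in s (0 when unknown).
#' @return An object of class `movement_time_model`.
#' @export
movement_time_model <- function(effector = c("hand", "eye"),
                                slope, intercept, sigma = 0) {
  effector <- match.arg(effector)
  keys <- tier_key(TARGET_RADII)
  expand <- function(v, what) {
    if (length(v) == 1L && is.null(names(v))) v <- setNames(rep(v, 3L), keys)
    if (!all(keys %in% names(v))) {
      stopf("%s must be a scalar or named by radius tier (%s)",
            what, paste(keys, collapse = ", "))
    }
    v[keys]
  }
  m <- structure(
    list(effector = effector,
         slope = expand(slope, "slope"),
         intercept = expand(intercept, "intercept"),
         sigma = expand(sigma, "sigma")),
    class = "movement_time_model"
  )
  # predictions must stay positive over the workspace (max distance < 0.35 m)
  worst <- m$intercept + pmin(m$slope * 0.35, 0)
  if (any(worst <= 0)) stopf("model predicts non-positive times in workspace")
  m
}

#' Default movement-time coefficients per effector
#'
#' Task-level mean coefficients: hand slope 1.0 s/m with intercept 0.2 s,
#' eye slope 0.9 s/m with intercept 0.3 s, applied to all three radius tiers
#' (per-size coefficients are fitted from data when available via
#' [fit_movement_time()]).
#'
#' @param effector `"hand"` or `"eye"`.
#' @return A `movement_time_model`.
#' @export
default_movement_model <- function(effector = c("hand", "eye")) {
  effector <- match.arg(effector)
  if (effector == "hand") {
    movement_time_model("hand", slope = 1.0, intercept = 0.2)
  } else {
    movement_time_model("eye", slope = 0.9, intercept = 0.3)
  }
}

#' Fit the movement-time model from harvest records
#'
#' Ordinary least-squares regression of inter-harvest duration on
#' center-to-center distance, computed separately per radius tier. Duration
#' is the time between successive successful harvests; distance the distance
#' between successive target centers. Records from the start-to-first-target
#' movement may be included.
#'
#' @param records Data frame with columns `distance` (m), `duration` (s) and
#'   `radius` (m, the radius of the harvested target).
#' @param effector `"hand"` or `"eye"`.
#' @return A `movement_time_model` with fitted `slope`, `intercept` and
#'   residual `sigma` per tier.
#' @export
fit_movement_time <- function(records, effector = c("hand", "eye")) {
  effector <- match.arg(effector)
  stopifnot(is.data.frame(records),
            all(c("distance", "duration", "radius") %in% names(records)))
  keys <- tier_key(TARGET_RADII)
  slope <- intercept <- sigma <- setNames(numeric(3L), keys)
  for (i in seq_along(TARGET_RADII)) {
    sel <- abs(records$radius - TARGET_RADII[i]) < 1e-9
    d <- records$distance[sel]
    y <- records$duration[sel]
    if (length(unique(d)) < 2L) {
      stopf("radius tier %s mm: need >= 2 distinct distances to fit", keys[i])
    }
    fit <- lm(y ~ d)
    slope[i] <- coef(fit)[["d"]]
    intercept[i] <- coef(fit)[["(Intercept)"]]
    sigma[i] <- if (length(d) > 2L)
      sqrt(sum(stats::residuals(fit)^2) / fit$df.residual) else 0
  }
  movement_time_model(effector, slope, intercept, sigma)
}

#' Predict movement time for a candidate harvest
#'
#' @param model A `movement_time_model`.
#' @param distance Distance(s) in metres (>= 0).
#' @param radius Radius tier(s) of the candidate target, in metres.
#' @return Predicted time(s) in seconds: `intercept + slope * distance` for
#'   the target's tier.
#' @export
predict_time <- function(model, distance, radius) {
  stopifnot(inherits(model, "movement_time_model"))
  if (any(distance < 0)) stopf("distance must be non-negative")
  key <- tier_key(radius)
  bad <- !key %in% names(model$slope)
  if (any(bad)) stopf("unknown radius tier: %s m", radius[bad][1])
  unname(model$intercept[key] + model$slope[key] * distance)
}

#' @export
print.movement_time_model <- function(x, ...) {
  cat(sprintf("<movement_time_model> effector '%s'\n", x$effector))
  print(data.frame(tier_mm = names(x$slope), slope = x$slope,
                   intercept = x$intercept, sigma = x$sigma,
                   row.names = NULL))
  invisible(x)
}
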