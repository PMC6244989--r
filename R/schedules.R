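#' Continuous within-run parameter schedule
#'
#' A linear ramp of a model parameter over the course of one simulation,
#' used to model the growth of the search in its later stages: reducing
#' the incremental angle `beta` raises the loop maxima, and reducing the
#' backward factor `b` (possibly below zero) raises the loop minima, so
#' the search pattern expands over time. Only `beta` and `b` can be
#' scheduled.
#'
#' @param param One of `"beta"` or `"b"`.
#' @param start,end Parameter value at step 0 and at step `n_steps`; the
#'   value is interpolated linearly in the step index between them.
#' @return An object of class `param_schedule`.
#' @examples
#' param_schedule("beta", 3, 1.8)
#' @seealso [value_at()], [simulate_scheduled()]
#' @export
param_schedule <- function(param = c("beta", "b"), start, end) {
  param <- match.arg(param)
  stopifnot(is.numeric(start), length(start) == 1L, is.finite(start),
            is.numeric(end), length(end) == 1L, is.finite(end))
  if (param == "b" && (start >= 1 || end >= 1))
    stop("scheduled backward factor must stay below 1", call. = FALSE)
  structure(list(param = param, start = as.numeric(start),
                 end = as.numeric(end)),
            class = "param_schedule")
}

#' Evaluate a schedule at a given step
#'
#' Linear interpolation `start + (end - start) * step / n_steps`; the
#' endpoints are met exactly at steps 0 and `n_steps`.
#'
#' @param schedule A [param_schedule()] object.
#' @param step Integer step index, `0 <= step <= n_steps` (vectorised).
#' @param n_steps Total number of steps of the run.
#' @return The interpolated parameter value(s).
#' @examples
#' sc <- param_schedule("beta", 3, 1.8)
#' value_at(sc, 0, 5000)     # 3
#' value_at(sc, 5000, 5000)  # 1.8
#' @export
value_at <- function(schedule, step, n_steps) {
  stopifnot(inherits(schedule, "param_schedule"))
  if (any(step < 0) || any(step > n_steps))
    stop("step index out of range 0..n_steps", call. = FALSE)
  schedule$start + (schedule$end - schedule$start) * step / n_steps
}

#' @export
print.param_schedule <- function(x, ...) {
  cat(sprintf("Schedule: %s ramps linearly %g -> %g over the run\n",
              x$param, x$start, x$end))
  invisible(x)
}

#' Simulate with scheduled parameters
#'
#' Runs [simulate_search()] with `beta` and/or `b` evaluated per step from
#' the given schedules. An empty schedule list reproduces the unscheduled
#' simulator bit for bit.
#'
#' @param params A [search_params()] object.
#' @param schedules A list of [param_schedule()] objects referencing
#'   distinct parameters.
#' @return A `search_trajectory`.
#' @examples
#' p <- search_params(alpha = 10, s = 0.12, b = 0.2, f = 0, n_steps = 2000)
#' tr <- simulate_scheduled(p, list(param_schedule("beta", 3, 1.8)))
#' @export
simulate_scheduled <- function(params, schedules) {
  simulate_search(params, schedules)
}

# Expand schedules into per-step beta and b vectors of length n_steps.
# The step from time t-1 to time t uses the values evaluated at step t-1
# (the time index of the state the step leaves from), so value_at(0) is
# the first value actually used, matching the stated start values.
resolve_schedules <- function(params, schedules) {
  n_steps <- params$n_steps
  beta <- rep(params$beta, n_steps)
  b <- rep(params$b, n_steps)
  if (is.null(schedules) || length(schedules) == 0L)
    return(list(beta = beta, b = b))
  if (inherits(schedules, "param_schedule")) schedules <- list(schedules)
  seen <- character(0)
  for (sc in schedules) {
    if (!inherits(sc, "param_schedule"))
      stop("schedules must be param_schedule objects", call. = FALSE)
    if (sc$param %in% seen)
      stop("duplicate schedule for parameter '", sc$param, "'",
           call. = FALSE)
    seen <- c(seen, sc$param)
    v <- value_at(sc, 0:(n_steps - 1L), n_steps)
    if (sc$param == "beta") beta <- v else b <- v
  }
  list(beta = beta, b = b)
}
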