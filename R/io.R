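#' Write and read trajectory CSV files
#'
#' Trajectories are written with the fixed header
#' `step,x,y,x_pert,y_pert,gamma_deg,r,r_pert`, one row per time index
#' (step 0 = initial state). Coordinates are written with 17 significant
#' digits so that a write-then-read round trip reproduces every double
#' bit-exactly.
#'
#' @param trajectory A `search_trajectory`.
#' @param path Output (or input) file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `search_trajectory` (without the
#'   producing parameters, which are not stored in the CSV).
#' @export
write_trajectory <- function(trajectory, path) {
  cols <- c("step", "x", "y", "x_pert", "y_pert", "gamma_deg", "r",
            "r_pert")
  stopifnot(all(cols %in% names(trajectory)))
  num <- function(v) sprintf("%.17g", v)
  lines <- paste(trajectory$step, num(trajectory$x), num(trajectory$y),
                 num(trajectory$x_pert), num(trajectory$y_pert),
                 num(trajectory$gamma_deg), num(trajectory$r),
                 num(trajectory$r_pert), sep = ",")
  writeLines(c(paste(cols, collapse = ","), lines), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = c(step = "integer"))
  expected <- c("step", "x", "y", "x_pert", "y_pert", "gamma_deg", "r",
                "r_pert")
  if (!identical(names(df), expected))
    stop("not a trajectory CSV: expected header ",
         paste(expected, collapse = ","), call. = FALSE)
  class(df) <- c("search_trajectory", "data.frame")
  df
}

#' Write loop metrics
#'
#' Writes the per-loop table `loop_index,start_step,end_step,max_r` and,
#' optionally, a JSON summary with `n_loops`, `max_r` and `mean_r`.
#'
#' @param summary A `loop_summary` from [segment_loops()] or
#'   [loop_summary()].
#' @param path Output CSV path.
#' @param json_path Optional path for the JSON summary.
#' @return `path`, invisibly.
#' @export
write_loop_metrics <- function(summary, path, json_path = NULL) {
  stopifnot(inherits(summary, "loop_summary"))
  ev <- summary$return_events
  starts <- if (length(ev)) c(0L, ev[-length(ev)]) else integer(0)
  df <- data.frame(loop_index = seq_along(ev), start_step = starts,
                   end_step = ev, max_r = summary$loop_maxima)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_loops = summary$n_loops,
           max_r = if (length(summary$loop_maxima))
                     max(summary$loop_maxima) else NA,
           mean_r = if (length(summary$loop_maxima))
                      mean(summary$loop_maxima) else NA),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read and write simulation configuration files
#'
#' Configurations are flat YAML with the keys `alpha, beta, s, b, f, n,
#' x0, y0, n_steps, seed` (all optional; omitted keys take the package
#' defaults) plus the optional `perturbation_mode` and a `schedules` block
#' with entries `{param, start, end}`.
#'
#' @param path Config file path.
#' @return `read_config()` returns a list with `params` and `schedules`,
#'   as [search_preset()]. `write_config()` returns `path` invisibly.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("alpha: 10", "beta: 3", "s: 0.12", "b: 0.2"), cfg)
#' read_config(cfg)$params
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("alpha", "beta", "s", "b", "f", "n", "x0", "y0", "n_steps",
             "seed", "perturbation_mode")
  extra <- setdiff(names(raw), c(known, "schedules"))
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  schedules <- list()
  if (!is.null(raw$schedules)) {
    schedules <- lapply(raw$schedules, function(e) {
      if (is.null(e$param) || is.null(e$start) || is.null(e$end))
        stop("each schedule entry needs param, start and end",
             call. = FALSE)
      param_schedule(e$param, e$start, e$end)
    })
  }
  params <- do.call(search_params, raw[intersect(known, names(raw))])
  list(params = params, schedules = schedules)
}

#' @rdname read_config
#' @param params A [search_params()] object to serialise.
#' @param schedules Optional list of [param_schedule()] objects.
#' @export
write_config <- function(params, path, schedules = NULL) {
  validate_params(params)
  out <- params[c("alpha", "beta", "s", "b", "f", "n", "x0", "y0",
                  "n_steps")]
  if (!is.null(params$seed)) out$seed <- params$seed
  out$perturbation_mode <- params$perturbation_mode
  if (!is.null(schedules) && length(schedules))
    out$schedules <- lapply(schedules, function(sc)
      list(param = sc$param, start = sc$start, end = sc$end))
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
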