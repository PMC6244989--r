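#' Moving-average smoothing of a trajectory
#'
#' Replaces the coordinates by centred moving averages of `window`
#' successive positions, mimicking the smoothing used when plotting
#' simulated patterns to suppress sharp corners caused by the finite
#' integration step. Both the raw and the perturbed coordinates are
#' smoothed; the distance columns are recomputed from the smoothed
#' coordinates. The smoothing is display/analysis only and never feeds
#' back into the dynamics.
#'
#' @param trajectory A `search_trajectory` (or any data frame with
#'   `step`, `x`, `y`, `x_pert`, `y_pert` columns).
#' @param window Odd positive window length; the default 5 averages five
#'   successive steps. `window = 1` is the identity.
#' @return A `search_trajectory` of length `nrow(trajectory) - window + 1`.
#' @examples
#' tr <- simulate_noiseless(search_params(n_steps = 200))
#' sm <- smooth_trajectory(tr)
#' nrow(sm) == nrow(tr) - 4
#' @export
smooth_trajectory <- function(trajectory, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer", call. = FALSE)
  if (nrow(trajectory) < window)
    stop("trajectory shorter than the smoothing window", call. = FALSE)
  if (window == 1L) return(trajectory)
  ma <- function(v) {
    out <- stats::filter(v, rep(1 / window, window), sides = 2)
    as.numeric(out[!is.na(out)])
  }
  half <- (window - 1L) %/% 2L
  keep <- (half + 1L):(nrow(trajectory) - half)
  g <- trajectory$gamma_deg[keep]
  new_trajectory(step = trajectory$step[keep],
                 x = ma(trajectory$x), y = ma(trajectory$y),
                 x_pert = ma(trajectory$x_pert),
                 y_pert = ma(trajectory$y_pert),
                 gamma_deg = g,
                 params = attr(trajectory, "params"),
                 schedules = attr(trajectory, "schedules"))
}

#' Distance-to-origin series of a trajectory
#'
#' The r/t diagram: the distance of the (perturbed) path to the origin at
#' every time index, the main device for comparing simulated and recorded
#' searches. For noiseless runs the perturbed coordinates equal the raw
#' ones.
#'
#' @param trajectory A `search_trajectory` (raw or smoothed).
#' @return An object of class `distance_series`: a data frame with
#'   columns `step` and `r`.
#' @examples
#' tr <- simulate_noiseless(search_params(n_steps = 500))
#' ds <- distance_series(tr)
#' head(ds)
#' @export
distance_series <- function(trajectory) {
  df <- data.frame(step = trajectory$step,
                   r = sqrt(trajectory$x_pert^2 + trajectory$y_pert^2))
  class(df) <- c("distance_series", "data.frame")
  df
}

#' Segment a distance series into loops
#'
#' A loop is one outbound-plus-inbound excursion: the search path runs out,
#' curves around and returns close to the origin before commencing the next
#' loop. Returns are detected on the distance series as local minima that
#' dip below `return_threshold` times the running maximum of `r`; the
#' running maximum (rather than the global one) is used so that searches
#' growing over time still register their early returns. One return event
#' is reported per below-threshold excursion (the sample where `r` is
#' smallest within each maximal run below the threshold; an excursion cut
#' off by the end of the series is not counted), so a single slow passage
#' near the origin — during which the series typically wiggles through
#' several micro-minima — counts as one return, not several;
#' `min_separation` additionally guards against events closer than that
#' many samples. Loop `k` is the segment from return `k - 1` (or the
#' series start) up to return `k`; the trailing incomplete segment after
#' the last return is not counted.
#'
#' @param series A `distance_series` (detection is typically run on a
#'   smoothed trajectory, see [loop_summary()]).
#' @param return_threshold Fraction of the running maximum below which a
#'   local minimum counts as a return to the origin; in `(0, 1)`,
#'   default 0.2.
#' @param min_separation Minimum number of samples between successive
#'   return events (default 5).
#' @return An object of class `loop_summary`: a list with
#'   `return_events` (step indices of the returns, strictly increasing),
#'   `loop_maxima` (max `r` within each loop), `loop_minima` (the `r`
#'   value at each return event) and `n_loops`.
#' @examples
#' ds <- data.frame(step = 0:500, r = abs(sin((0:500) / 20)))
#' class(ds) <- c("distance_series", "data.frame")
#' segment_loops(ds)$n_loops
#' @export
segment_loops <- function(series, return_threshold = 0.2,
                          min_separation = 5L) {
  if (nrow(series) == 0L) stop("empty distance series", call. = FALSE)
  if (return_threshold <= 0 || return_threshold >= 1)
    stop("return_threshold must lie strictly between 0 and 1",
         call. = FALSE)
  r <- series$r
  m <- length(r)
  runmax <- cummax(r)
  below <- r < return_threshold * runmax
  events <- integer(0)
  last <- -Inf
  if (any(below)) {
    # maximal runs of consecutive below-threshold samples
    rl <- rle(below)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$values)) {
      # an excursion cut off by the series end has not demonstrably turned
      # back outward; it is not counted as a completed return
      if (ends[k] == m) next
      seg <- starts[k]:ends[k]
      idx <- seg[which.min(r[seg])]
      if (idx - last >= min_separation) {
        events <- c(events, idx)
        last <- idx
      }
    }
  }
  if (length(events) == 0L) {
    out <- list(return_events = integer(0), loop_maxima = numeric(0),
                loop_minima = numeric(0), n_loops = 0L)
  } else {
    starts <- c(1L, events[-length(events)])
    loop_max <- mapply(function(a, z) max(r[a:z]), starts, events)
    out <- list(return_events = series$step[events],
                loop_maxima = as.numeric(loop_max),
                loop_minima = r[events],
                n_loops = length(events))
  }
  out$return_threshold <- return_threshold
  class(out) <- "loop_summary"
  out
}

#' Loop metrics of a trajectory
#'
#' Convenience pipeline: smooth the trajectory, take its distance-to-origin
#' series and segment it into loops.
#'
#' @param trajectory A `search_trajectory`.
#' @param window Smoothing window passed to [smooth_trajectory()].
#' @param return_threshold,min_separation Passed to [segment_loops()].
#' @return A `loop_summary`.
#' @examples
#' tr <- simulate_noiseless(search_params(b = 0.2, n_steps = 2000))
#' loop_summary(tr)
#' @export
loop_summary <- function(trajectory, window = 5L, return_threshold = 0.2,
                         min_separation = 5L) {
  sm <- smooth_trajectory(trajectory, window)
  segment_loops(distance_series(sm), return_threshold, min_separation)
}

#' @export
print.loop_summary <- function(x, ...) {
  cat(sprintf("Loop summary: %d loops (threshold %.2g x running max)\n",
              x$n_loops, x$return_threshold))
  if (x$n_loops > 0) {
    cat(sprintf("  return events at steps: %s\n",
                paste(x$return_events, collapse = ", ")))
    cat(sprintf("  loop maxima: %s\n",
                paste(sprintf("%.3g", x$loop_maxima), collapse = ", ")))
  }
  invisible(x)
}
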