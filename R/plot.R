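#' Plot a search trajectory with its r/t diagram
#'
#' Draws the (perturbed, optionally smoothed) search pattern in the top
#' panel with the origin marked, and the distance-to-origin series in the
#' bottom panel — the layout used throughout the field to compare
#' simulated and recorded searches.
#'
#' @param x A `search_trajectory`.
#' @param window Smoothing window applied before plotting (default 5, the
#'   standard five-step average; 1 disables smoothing).
#' @param main Optional title.
#' @param ... Further arguments passed to the path `plot()` call.
#' @return `x`, invisibly.
#' @export
plot.search_trajectory <- function(x, window = 5L, main = NULL, ...) {
  tr <- if (window > 1L && nrow(x) >= window)
    smooth_trajectory(x, window) else x
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$x_pert, tr$y_pert, type = "l", asp = 1,
                 xlab = "x", ylab = "y", main = main, ...)
  graphics::points(0, 0, pch = 3, cex = 1.2)
  graphics::plot(tr$step, tr$r_pert, type = "l",
                 xlab = "integration step t", ylab = "distance r")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# Render a trajectory panel to a PNG file (used by the CLI).
save_trajectory_plot <- function(trajectory, path, window = 5L,
                                 main = NULL) {
  grDevices::png(path, width = 800, height = 900)
  on.exit(grDevices::dev.off())
  plot(trajectory, window = window, main = main)
  invisible(path)
}
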