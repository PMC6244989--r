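#' Model parameters for a centred-loop search simulation
#'
#' Bundles the eight model parameters together with run length, RNG seed and
#' the perturbation feedback mode into a validated `search_params` object.
#'
#' The deterministic skeleton of the model is a loop around the origin: at
#' every integration step the angle `gamma` between the home vector and the
#' step direction grows by the incremental angle `beta`, the animal moves a
#' step of length `s`, and the radial component of the step is reduced by
#' `|cos(gamma)| * b` (the backward factor), which straightens inbound legs
#' and re-centres the loops on the origin. Gaussian perturbations of scale
#' `f` are applied in blocks of `n` steps with a sine envelope.
#'
#' @param alpha Initial step-direction angle \eqn{\gamma_0} in degrees.
#' @param beta Incremental angle added to \eqn{\gamma} at every integration
#'   step, in degrees. Smaller `beta` gives larger loops.
#' @param s Integration step length (arbitrary length units per step);
#'   must be positive. An integration step is a model time unit, not a
#'   physical ant step.
#' @param b Backward factor (dimensionless), must satisfy `b < 1`; may be
#'   negative. `b > 0` straightens inbound legs so loops return to the
#'   origin; `b = 0` yields a non-returning "spinning top" pattern.
#' @param f Random perturbation factor (length units), `f >= 0`. `f = 0`
#'   reduces the simulator exactly to the noiseless dynamics.
#' @param n Number of integration steps per perturbation block (positive
#'   integer). One Gaussian displacement vector is drawn per block.
#' @param x0,y0 Initial position (length units). Must not both be zero:
#'   the origin is a coordinate singularity.
#' @param n_steps Total number of integration steps (positive integer).
#' @param seed Optional integer RNG seed; `NULL` leaves the RNG state alone.
#' @param perturbation_mode Either `"transient"` (default: the accumulated
#'   state stays noiseless-additive while step directions are evaluated at
#'   the perturbed position) or `"persistent"` (the perturbed position
#'   permanently replaces the state). See the methods vignette.
#'
#' @return An object of class `search_params` (a named list).
#' @examples
#' p <- search_params(alpha = 10, beta = 3, s = 0.12, b = 0.2)
#' p
#' @seealso [simulate_search()], [search_preset()]
#' @export
search_params <- function(alpha = 10, beta = 3, s = 0.12, b = 0.2,
                          f = 0, n = 3L, x0 = 0.01, y0 = 0,
                          n_steps = 5000L, seed = NULL,
                          perturbation_mode = c("transient", "persistent")) {
  perturbation_mode <- match.arg(perturbation_mode)
  p <- list(alpha = as.numeric(alpha), beta = as.numeric(beta),
            s = as.numeric(s), b = as.numeric(b), f = as.numeric(f),
            n = as.integer(n), x0 = as.numeric(x0), y0 = as.numeric(y0),
            n_steps = as.integer(n_steps),
            seed = if (is.null(seed)) NULL else as.integer(seed),
            perturbation_mode = perturbation_mode)
  class(p) <- "search_params"
  validate_params(p)
  p
}

#' Validate a `search_params` object
#'
#' Checks the model's parameter constraints: `b < 1`, `s > 0`, `n >= 1`,
#' `f >= 0`, a non-zero initial position and a positive run length.
#'
#' @param p A `search_params` object (or plain named list with the same
#'   fields).
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(p) {
  scalar_num <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (field in c("alpha", "beta", "s", "b", "f", "x0", "y0")) {
    if (!scalar_num(p[[field]]))
      stop("parameter '", field, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  if (p$b >= 1)
    stop("backward factor b must satisfy b < 1 (got b = ", p$b, ")",
         call. = FALSE)
  if (p$s <= 0)
    stop("integration step length s must be positive", call. = FALSE)
  if (p$f < 0)
    stop("perturbation factor f must be non-negative", call. = FALSE)
  if (!is.numeric(p$n) || length(p$n) != 1L || is.na(p$n) || p$n < 1)
    stop("block length n must be a positive integer", call. = FALSE)
  if (!is.numeric(p$n_steps) || length(p$n_steps) != 1L ||
      is.na(p$n_steps) || p$n_steps < 1)
    stop("n_steps must be a positive integer", call. = FALSE)
  if (p$x0 == 0 && p$y0 == 0)
    stop("initial position (x0, y0) must not be the origin: ",
         "the azimuth direction is undefined there", call. = FALSE)
  invisible(p)
}

#' @export
print.search_params <- function(x, ...) {
  cat("Centred-loop search parameters\n")
  cat(sprintf("  alpha = %g deg   beta = %g deg   s = %g   b = %g\n",
              x$alpha, x$beta, x$s, x$b))
  cat(sprintf("  f = %g   n = %d   (x0, y0) = (%g, %g)\n",
              x$f, x$n, x$x0, x$y0))
  cat(sprintf("  n_steps = %d   seed = %s   mode = %s\n",
              x$n_steps,
              if (is.null(x$seed)) "none" else as.character(x$seed),
              x$perturbation_mode))
  invisible(x)
}

# Merge user overrides into an existing params object, revalidating.
modify_params <- function(p, ...) {
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  for (nm in names(dots)) {
    if (!nm %in% c(names(p))) stop("unknown parameter '", nm, "'")
    p[[nm]] <- dots[[nm]]
  }
  do.call(search_params, p[setdiff(names(p), character(0))])
}
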