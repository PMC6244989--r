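# Internal trajectory constructor: a data.frame with one row per time index
# (row 1 = step 0, the initial state) and the producing parameters attached.
new_trajectory <- function(step, x, y, x_pert, y_pert, gamma_deg,
                           params, schedules = NULL) {
  df <- data.frame(step = step, x = x, y = y,
                   x_pert = x_pert, y_pert = y_pert,
                   gamma_deg = gamma_deg,
                   r = sqrt(x^2 + y^2),
                   r_pert = sqrt(x_pert^2 + y_pert^2))
  attr(df, "params") <- params
  attr(df, "schedules") <- schedules
  class(df) <- c("search_trajectory", "data.frame")
  df
}

#' Simulate a centred-loop systematic search
#'
#' The full stochastic simulator. Starting from `(x0, y0)` with
#' `gamma = alpha`, each integration step:
#' \enumerate{
#'   \item advances the perturbation block (a fresh Gaussian displacement
#'     vector `p = (f psi_k, f psi_k+1)` is drawn at the start of every
#'     block of `n` steps, x-component first);
#'   \item forms the perturbed position `u' = u + sin(i pi / (n + 1)) p`
#'     from the current state and the active block;
#'   \item evaluates the local radial/tangential unit vectors and the
#'     radius at `u'` (the perturbation feeds back into the turning);
#'   \item adds the step displacement
#'     `s (cos g - |cos g| b) e_r + s sin(g) e_phi` to the state;
#'   \item advances `gamma` by `beta`.
#' }
#' With `perturbation_mode = "transient"` (default) the accumulated state
#' stays noiseless-additive and the perturbation acts as a transient offset
#' with the sine envelope; with `"persistent"` the perturbed position
#' replaces the state. With `f = 0` the run is exactly the noiseless
#' dynamics and the perturbed columns equal the raw ones.
#'
#' @param params A [search_params()] object. If `params$seed` is non-NULL
#'   the RNG is seeded at the start of the run, making the trajectory
#'   reproducible.
#' @param schedules Optional list of [param_schedule()] objects giving
#'   continuous within-run ramps of `beta` and/or `b`.
#' @return A `search_trajectory`: a data frame with `n_steps + 1` rows and
#'   columns `step`, `x`, `y` (accumulated state), `x_pert`, `y_pert`
#'   (perturbed path, the one analysed and plotted), `gamma_deg` (the angle
#'   state at that time index; the step into row `t + 1` uses row `t`'s
#'   angle), `r` and `r_pert` (distances to the origin). The producing
#'   parameters are attached as attributes.
#' @examples
#' p <- search_params(b = 0.2, f = 0.1, n = 3, n_steps = 1000, seed = 1)
#' tr <- simulate_search(p)
#' summary(tr$r_pert)
#' @seealso [simulate_noiseless()], [simulate_polar()], [loop_summary()]
#' @export
simulate_search <- function(params, schedules = NULL) {
  validate_params(params)
  sched <- resolve_schedules(params, schedules)
  if (!is.null(params$seed)) set.seed(params$seed)

  n_steps <- params$n_steps
  s <- params$s
  f <- params$f
  n_blk <- params$n
  persistent <- identical(params$perturbation_mode, "persistent")
  deg <- pi / 180

  x <- numeric(n_steps + 1L); y <- numeric(n_steps + 1L)
  xp <- numeric(n_steps + 1L); yp <- numeric(n_steps + 1L)
  gam <- numeric(n_steps + 1L)

  ux <- params$x0; uy <- params$y0
  gamma <- params$alpha %% 360
  x[1L] <- ux; y[1L] <- uy; xp[1L] <- ux; yp[1L] <- uy; gam[1L] <- gamma

  px <- 0; py <- 0; i_blk <- 0L

  for (t in seq_len(n_steps)) {
    if (f > 0) {
      i_blk <- i_blk + 1L
      if (i_blk > n_blk) i_blk <- 1L
      if (i_blk == 1L) {
        psi <- stats::rnorm(2L)
        px <- f * psi[1L]
        py <- f * psi[2L]
      }
      env <- sin(min(i_blk, n_blk + 1L - i_blk) * pi / (n_blk + 1))
      upx <- ux + env * px
      upy <- uy + env * py
    } else {
      env <- 0
      upx <- ux
      upy <- uy
    }

    # arbitrarily small r is tolerated (the step is taken from the current
    # direction vectors); only an exact zero is a true singularity
    r <- sqrt(upx * upx + upy * upy)
    if (r == 0)
      stop("trajectory reached the origin exactly at step ", t,
           ": azimuth undefined, cannot continue", call. = FALSE)

    g <- gamma * deg
    cg <- cos(g)
    fac <- s * (cg - abs(cg) * sched$b[t])
    tg <- s * sin(g)
    dx <- (fac * upx - tg * upy) / r
    dy <- (fac * upy + tg * upx) / r

    if (persistent) {
      ux <- upx + dx
      uy <- upy + dy
    } else {
      ux <- ux + dx
      uy <- uy + dy
    }

    gamma <- (gamma + sched$beta[t]) %% 360

    x[t + 1L] <- ux; y[t + 1L] <- uy
    xp[t + 1L] <- ux + env * px
    yp[t + 1L] <- uy + env * py
    gam[t + 1L] <- gamma
  }

  new_trajectory(step = 0:n_steps, x = x, y = y, x_pert = xp, y_pert = yp,
                 gamma_deg = gam, params = params, schedules = schedules)
}

#' @export
print.search_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Search trajectory: %d steps", nrow(x) - 1L))
  if (!is.null(p))
    cat(sprintf(" (alpha=%g, beta=%g, s=%g, b=%g, f=%g, n=%d)",
                p$alpha, p$beta, p$s, p$b, p$f, p$n))
  cat("\n")
  cat(sprintf("  max r = %.4g, final r = %.4g\n",
              max(x$r_pert), x$r_pert[nrow(x)]))
  if (!is.null(attr(x, "schedules")) && length(attr(x, "schedules")))
    cat("  with scheduled parameters:",
        paste(vapply(attr(x, "schedules"), function(s) s$param,
                     character(1)), collapse = ", "), "\n")
  invisible(x)
}
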