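#' Advance the step-direction angle by the incremental angle
#'
#' The angle `gamma` between the home-vector direction and the step
#' direction grows by a constant `beta` at every integration step. The
#' result is wrapped into `[0, 360)` degrees; wrapping is mathematically
#' inert (all trigonometric evaluations are periodic) but keeps the state
#' bounded over long runs.
#'
#' @param gamma Current angle in degrees.
#' @param beta Incremental angle in degrees.
#' @return The advanced, wrapped angle in degrees.
#' @examples
#' update_gamma(10, 3)   # 13
#' update_gamma(359, 3)  # 2
#' @export
update_gamma <- function(gamma, beta) {
  (gamma + beta) %% 360
}

#' Radial scaling of a step: the backward-factor term
#'
#' The radial component of every step is `s * (cos(gamma) - |cos(gamma)| * b)`.
#' This returns the dimensionless factor `cos(gamma) - |cos(gamma)| * b`.
#' On inbound headings (`cos(gamma) = -a < 0`) it equals `-a (1 + b)`, so
#' the distance to the origin shrinks faster and the turn per step is
#' smaller (straighter approach); on outbound headings (`cos(gamma) = +a`)
#' it equals `+a (1 - b)`, so the distance grows more slowly. This asymmetry
#' is what makes loops re-centre on the origin.
#'
#' @param gamma Angle in degrees between the radial direction and the step.
#' @param b Backward factor, `b < 1`.
#' @return Dimensionless signed radial factor.
#' @examples
#' radial_factor(180, 0.2)  # -1.2  = -(1 + b)
#' radial_factor(0, 0.2)    #  0.8  = +(1 - b)
#' @export
radial_factor <- function(gamma, b) {
  cg <- cos(gamma * pi / 180)
  cg - abs(cg) * b
}

#' Local radial and tangential unit vectors at a position
#'
#' In the moving polar frame attached to position `u = (x, y)`, the radial
#' unit vector points away from the origin and the tangential unit vector
#' is the radial one rotated +90 degrees (counter-clockwise).
#'
#' @param u Numeric length-2 position vector `(x, y)`; must be non-zero.
#' @return A list with components `e_r` and `e_phi`, each a numeric
#'   length-2 unit vector.
#' @examples
#' unit_vectors(c(3, 4))  # e_r = (0.6, 0.8), e_phi = (-0.8, 0.6)
#' @export
unit_vectors <- function(u) {
  r <- sqrt(u[1]^2 + u[2]^2)
  if (r == 0)
    stop("position is at the origin: the azimuth direction is undefined, ",
         "cannot compute a movement from (0, 0)", call. = FALSE)
  list(e_r = c(u[1] / r, u[2] / r), e_phi = c(-u[2] / r, u[1] / r))
}

#' One integration-step displacement in the Cartesian frame
#'
#' The displacement is the sum of a radial part
#' `s * (cos(gamma) - |cos(gamma)| b) * e_r` and a tangential part
#' `s * sin(gamma) * e_phi`, with the local unit vectors evaluated at `u`.
#' Add it to the current position to advance one step.
#'
#' @param u Numeric length-2 position vector; must be non-zero.
#' @param gamma Step-direction angle in degrees.
#' @param params A [search_params()] object (only `s` and `b` are used).
#' @return Numeric length-2 displacement vector.
#' @examples
#' p <- search_params(s = 0.12, b = 0.2)
#' cartesian_step(c(1, 0), 180, p)  # (-0.144, 0)
#' @export
cartesian_step <- function(u, gamma, params) {
  e <- unit_vectors(u)
  g <- gamma * pi / 180
  params$s * radial_factor(gamma, params$b) * e$e_r +
    params$s * sin(g) * e$e_phi
}

#' One integration step in polar coordinates
#'
#' The polar formulation serves as an independent oracle for the Cartesian
#' integrator. The step has local components
#' `d_par  = s * (cos(gamma) - |cos(gamma)| b)` along the radial direction
#' and `d_perp = s * sin(gamma)` along the tangential direction.
#'
#' Two update rules are provided. `method = "exact"` performs the vector
#' sum in polar coordinates,
#' `r' = sqrt((r + d_par)^2 + d_perp^2)`,
#' `phi' = phi + atan2(d_perp, r + d_par)`,
#' which is the identical operation to adding the Cartesian displacement
#' and agrees with [cartesian_step()] to machine precision.
#' `method = "linearised"` uses the first-order textbook projection
#' `r' = r + d_par`, `phi' = phi + d_perp / r` (the division by `r`
#' compensates the unequal metric of polar coordinates: turning is more
#' rapid close to the origin). The linearised rule agrees with the exact
#' one only to first order in `s / r`.
#'
#' @param r Distance to origin (must be positive).
#' @param phi Azimuth in radians.
#' @param gamma Step-direction angle in degrees.
#' @param params A [search_params()] object (only `s` and `b` are used).
#' @param method `"exact"` (default) or `"linearised"`.
#' @return Named numeric vector `c(r = ..., phi = ...)` after the step.
#' @examples
#' p <- search_params(s = 0.12, b = 0)
#' polar_step(1, 0, 90, p, method = "linearised")  # dphi = 0.12 rad
#' @export
polar_step <- function(r, phi, gamma, params,
                       method = c("exact", "linearised")) {
  method <- match.arg(method)
  if (r <= 0)
    stop("polar radius must be positive (origin singularity)",
         call. = FALSE)
  g <- gamma * pi / 180
  d_par <- params$s * radial_factor(gamma, params$b)
  d_perp <- params$s * sin(g)
  if (method == "exact") {
    r_new <- sqrt((r + d_par)^2 + d_perp^2)
    phi_new <- phi + atan2(d_perp, r + d_par)
  } else {
    r_new <- r + d_par
    phi_new <- phi + d_perp / r
  }
  if (r_new <= 0)
    stop("polar step crossed the origin (r <= 0): singularity",
         call. = FALSE)
  c(r = r_new, phi = phi_new)
}

#' Simulate the noiseless centred-loop dynamics
#'
#' Runs the deterministic skeleton of the model: starting from `(x0, y0)`
#' with `gamma = alpha`, each step moves by [cartesian_step()] evaluated at
#' the current position and then advances `gamma` by `beta`. Equivalent to
#' [simulate_search()] with `f = 0`; any `f` in `params` is ignored.
#'
#' @param params A [search_params()] object.
#' @param schedules Optional list of [param_schedule()] objects.
#' @return A `search_trajectory` (see [simulate_search()]).
#' @examples
#' tr <- simulate_noiseless(search_params(b = 0.2, n_steps = 500))
#' range(tr$r)
#' @export
simulate_noiseless <- function(params, schedules = NULL) {
  params$f <- 0
  simulate_search(params, schedules)
}

#' Simulate the noiseless dynamics in the polar formulation (oracle)
#'
#' Integrates the same noiseless dynamics as [simulate_noiseless()] but in
#' `(r, phi)` state variables, using [polar_step()]. With
#' `method = "exact"` the trajectory coincides with the Cartesian one to
#' floating-point accuracy, making this an independent cross-check of the
#' production integrator. Only noiseless runs are supported.
#'
#' @param params A [search_params()] object; `f` must be 0.
#' @param schedules Optional list of [param_schedule()] objects.
#' @param method Passed to [polar_step()].
#' @return A `search_trajectory` with positions converted back to `(x, y)`.
#' @export
simulate_polar <- function(params, schedules = NULL,
                           method = c("exact", "linearised")) {
  method <- match.arg(method)
  validate_params(params)
  if (params$f != 0)
    stop("the polar oracle only supports noiseless runs (f = 0)",
         call. = FALSE)
  sched <- resolve_schedules(params, schedules)
  n_steps <- params$n_steps
  r <- sqrt(params$x0^2 + params$y0^2)
  phi <- atan2(params$y0, params$x0)
  gamma <- params$alpha %% 360
  out_r <- numeric(n_steps + 1L)
  out_phi <- numeric(n_steps + 1L)
  out_g <- numeric(n_steps + 1L)
  out_r[1L] <- r; out_phi[1L] <- phi; out_g[1L] <- gamma
  sp <- params
  for (t in seq_len(n_steps)) {
    sp$b <- sched$b[t]
    st <- polar_step(r, phi, gamma, sp, method = method)
    r <- st[["r"]]; phi <- st[["phi"]]
    gamma <- update_gamma(gamma, sched$beta[t])
    out_r[t + 1L] <- r; out_phi[t + 1L] <- phi; out_g[t + 1L] <- gamma
  }
  x <- out_r * cos(out_phi)
  y <- out_r * sin(out_phi)
  new_trajectory(step = 0:n_steps, x = x, y = y, x_pert = x, y_pert = y,
                 gamma_deg = out_g, params = params, schedules = schedules)
}
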