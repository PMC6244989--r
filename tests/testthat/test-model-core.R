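test_that("parameter validation enforces the model constraints", {
  expect_s3_class(search_params(), "search_params")
  expect_error(search_params(b = 1), "b < 1")
  expect_error(search_params(b = 1.5), "b < 1")
  expect_no_error(search_params(b = -0.03))  # negative b is allowed
  expect_error(search_params(s = 0), "positive")
  expect_error(search_params(s = -0.1), "positive")
  expect_error(search_params(f = -0.1), "non-negative")
  expect_error(search_params(n = 0), "positive integer")
  expect_error(search_params(x0 = 0, y0 = 0), "origin")
  expect_error(search_params(n_steps = 0), "positive integer")
})

test_that("update_gamma adds beta and wraps into [0, 360)", {
  expect_equal(update_gamma(10, 3), 13)
  expect_equal(update_gamma(359, 3), 2)
  expect_equal(update_gamma(13, 0), 13)
  # wrapping never changes the trig evaluation
  g <- seq(-720, 1080, by = 37.3)
  expect_equal(cos(update_gamma(g, 123.4) * pi / 180),
               cos((g + 123.4) * pi / 180),
               tolerance = 1e-12)
})

test_that("radial_factor implements the backward-factor asymmetry", {
  expect_equal(radial_factor(180, 0.2), -1.2)  # inbound: -(1 + b)
  expect_equal(radial_factor(0, 0.2), 0.8)     # outbound: +(1 - b)
  expect_equal(radial_factor(90, 0.7), 0, tolerance = 1e-15)
  # with b = 0 the components conserve the step magnitude
  g <- runif(50, 0, 360)
  expect_equal(radial_factor(g, 0)^2 + sin(g * pi / 180)^2,
               rep(1, 50), tolerance = 1e-12)
})

test_that("unit_vectors gives an orthonormal moving frame", {
  uv <- unit_vectors(c(3, 4))
  expect_equal(uv$e_r, c(0.6, 0.8))
  expect_equal(uv$e_phi, c(-0.8, 0.6))
  uv <- unit_vectors(c(1, 0))
  expect_equal(uv$e_r, c(1, 0))
  expect_equal(uv$e_phi, c(0, 1))  # +90 degrees counter-clockwise
  expect_error(unit_vectors(c(0, 0)), "origin")
  # orthonormality for random positions
  set.seed(7)
  for (k in 1:20) {
    u <- rnorm(2)
    uv <- unit_vectors(u)
    expect_equal(sum(uv$e_r^2), 1, tolerance = 1e-12)
    expect_equal(sum(uv$e_phi^2), 1, tolerance = 1e-12)
    expect_equal(sum(uv$e_r * uv$e_phi), 0, tolerance = 1e-12)
  }
})

test_that("cartesian_step matches the forced displacement examples", {
  p <- search_params(s = 0.12, b = 0)
  expect_equal(cartesian_step(c(1, 0), 0, p), c(0.12, 0),
               tolerance = 1e-15)
  expect_equal(cartesian_step(c(1, 0), 90, p), c(0, 0.12),
               tolerance = 1e-15)
  p2 <- search_params(s = 0.12, b = 0.2)
  expect_equal(cartesian_step(c(1, 0), 90, p2), c(0, 0.12),
               tolerance = 1e-15)  # radial term vanishes at 90 degrees
  expect_equal(cartesian_step(c(1, 0), 180, p2), c(-0.144, 0),
               tolerance = 1e-15)
  expect_error(cartesian_step(c(0, 0), 10, p), "origin")
})

test_that("linearised polar step reproduces the textbook projections", {
  p <- search_params(s = 0.12, b = 0)
  st <- polar_step(1, 0, 90, p, method = "linearised")
  expect_equal(unname(st["r"]), 1)
  expect_equal(unname(st["phi"]), 0.12)  # radians
  # turning twice as fast at half the radius
  st2 <- polar_step(0.5, 0, 90, p, method = "linearised")
  expect_equal(unname(st2["phi"]), 0.24)
  expect_error(polar_step(0, 0, 10, p), "positive")
})

test_that("exact polar step equals one cartesian step for random inputs", {
  set.seed(11)
  for (k in 1:25) {
    r <- runif(1, 0.2, 5); phi <- runif(1, -pi, pi)
    gamma <- runif(1, 0, 360)
    p <- search_params(s = runif(1, 0.01, 0.3), b = runif(1, -0.3, 0.9))
    u <- c(r * cos(phi), r * sin(phi))
    u_new <- u + cartesian_step(u, gamma, p)
    st <- polar_step(r, phi, gamma, p, method = "exact")
    expect_equal(unname(st["r"] * cos(st["phi"])), u_new[1],
                 tolerance = 1e-12)
    expect_equal(unname(st["r"] * sin(st["phi"])), u_new[2],
                 tolerance = 1e-12)
  }
})

test_that("polar and Cartesian integrators agree (frame equivalence)", {
  set.seed(3)
  for (k in 1:4) {
    p <- search_params(alpha = runif(1, 0, 360), beta = runif(1, 1, 5),
                       s = runif(1, 0.03, 0.15), b = runif(1, 0.05, 0.5),
                       x0 = 0.01, y0 = 0.005, n_steps = 2000L)
    tc <- simulate_noiseless(p)
    tp <- simulate_polar(p, method = "exact")
    scale <- max(tc$r)
    expect_lt(max(abs(tc$x - tp$x), abs(tc$y - tp$y)) / scale, 1e-8)
  }
})

test_that("noiseless run has the documented shape and determinism", {
  p <- ref_params(b = 0.2, n_steps = 1000L)
  tr <- simulate_noiseless(p)
  expect_s3_class(tr, "search_trajectory")
  expect_equal(nrow(tr), 1001L)           # n_steps + 1 incl. initial state
  expect_identical(tr$step, 0:1000)
  expect_true(all(tr$r > 0))
  expect_equal(tr$x[1], 0.01)
  expect_equal(tr$gamma_deg[1], 10)       # gamma_0 = alpha
  expect_identical(tr$x_pert, tr$x)       # f = 0: perturbed = raw
  # bit-identical repetition
  tr2 <- simulate_noiseless(p)
  expect_identical(tr$x, tr2$x)
  expect_identical(tr$y, tr2$y)
})

test_that("with b = 0 every step displacement has length exactly s", {
  p <- ref_params(b = 0, n_steps = 800L)
  tr <- simulate_noiseless(p)
  d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_true(all(abs(d - p$s) < 1e-12))
})

test_that("noiseless trajectories are rotationally equivariant", {
  p <- ref_params(n_steps = 1500L)
  t1 <- simulate_noiseless(p)
  for (theta in c(0.7, 2.3)) {
    u0 <- rotate_xy(p$x0, p$y0, theta)
    t2 <- simulate_noiseless(ref_params(n_steps = 1500L, x0 = u0$x,
                                        y0 = u0$y))
    ref <- rotate_xy(t1$x, t1$y, theta)
    expect_lt(max(abs(t2$x - ref$x), abs(t2$y - ref$y)), 1e-9)
  }
})

test_that("negating alpha and beta mirrors the trajectory", {
  t1 <- simulate_noiseless(ref_params(n_steps = 1500L))
  t2 <- simulate_noiseless(search_params(alpha = -10, beta = -3,
                                         s = 0.12, b = 0.2, x0 = 0.01,
                                         y0 = 0, n_steps = 1500L))
  expect_equal(t2$x, t1$x, tolerance = 1e-9)
  expect_equal(t2$y, -t1$y, tolerance = 1e-9)
})

test_that("loop geometry is insensitive to |u0| after the first loop", {
  maxima <- lapply(c(0.001, 0.01, 0.05), function(x0) {
    tr <- simulate_noiseless(ref_params(n_steps = 2000L, x0 = x0))
    loop_summary(tr)$loop_maxima
  })
  # the attractor loop size (3rd loop onwards) agrees across seeds of u0
  for (k in 2:3) {
    expect_equal(maxima[[k]][3:8], maxima[[1]][3:8], tolerance = 1e-4)
  }
})

test_that("loop size grows with s and shrinks with beta", {
  max_r_s <- vapply(c(0.04, 0.07, 0.12), function(s) {
    max(simulate_noiseless(search_params(s = s, b = 0.2,
                                         n_steps = 3000L))$r)
  }, numeric(1))
  expect_true(all(diff(max_r_s) > 0))
  max_r_beta <- vapply(c(3, 2, 1.8), function(beta) {
    max(simulate_noiseless(search_params(beta = beta, b = 0.2,
                                         n_steps = 3000L))$r)
  }, numeric(1))
  expect_true(all(diff(max_r_beta) > 0))  # decreasing beta: larger loops
})
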