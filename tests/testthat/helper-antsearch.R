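# Shared fixtures: the reference parameter set of the published sweep
# figures (alpha = 10, beta = 3, s = 0.12, n = 3) with a configurable
# backward factor, and a rotation helper for the symmetry tests.

ref_params <- function(b = 0.2, f = 0, n_steps = 5000L, seed = NULL,
                       x0 = 0.01, y0 = 0, ...) {
  search_params(alpha = 10, beta = 3, s = 0.12, b = b, f = f, n = 3L,
                x0 = x0, y0 = y0, n_steps = n_steps, seed = seed, ...)
}

rotate_xy <- function(x, y, theta) {
  list(x = cos(theta) * x - sin(theta) * y,
       y = sin(theta) * x + cos(theta) * y)
}

# Coefficient of variation
cv <- function(x) stats::sd(x) / mean(x)

# Per-seed loop maxima for the reference parameters at a given f
loop_maxima_by_seed <- function(f, seeds, n_steps = 5000L) {
  lapply(seeds, function(sd) {
    tr <- simulate_search(ref_params(f = f, seed = sd, n_steps = n_steps))
    loop_summary(tr)$loop_maxima
  })
}
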