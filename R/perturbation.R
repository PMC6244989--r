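#' Draw one perturbation block
#'
#' A perturbation block covers `n` consecutive integration steps. At its
#' start exactly two standard-normal numbers are consumed from the RNG
#' stream: the first scales the x-component, the second the y-component of
#' the block's displacement vector `p = (f psi_k, f psi_k+1)`. The same
#' vector is then applied over the whole block with the sine envelope of
#' [envelope()].
#'
#' @param f Perturbation factor (length units), `f >= 0`. With `f = 0` the
#'   vector is exactly `(0, 0)` (the draws are still consumed so that the
#'   RNG stream position is independent of `f`).
#' @param n Block length in steps (positive integer).
#' @return An object of class `perturbation_block`: a list with the
#'   displacement vector `p`, the within-block index `i` (initialised to
#'   1), and the block length `n`.
#' @examples
#' set.seed(1)
#' draw_block(0.1, 3)
#' @export
draw_block <- function(f, n) {
  if (f < 0) stop("f must be non-negative", call. = FALSE)
  if (n < 1) stop("block length n must be >= 1", call. = FALSE)
  psi <- stats::rnorm(2L)
  blk <- list(p = c(f * psi[1L], f * psi[2L]), i = 1L, n = as.integer(n))
  class(blk) <- "perturbation_block"
  blk
}

#' Sine envelope of a perturbation block
#'
#' Within a block of `n` steps the displacement vector is scaled by
#' `sin(i pi / (n + 1))` at within-block step `i`: the perturbation grows
#' to full strength mid-block and fades out again, so each block is a
#' transient excursion rather than a permanent jump. The envelope is
#' strictly positive on `1..n` and symmetric,
#' `envelope(i, n) == envelope(n + 1 - i, n)`. The symmetry holds exactly
#' in floating point: the sine is evaluated at the folded index
#' `min(i, n + 1 - i)`, which is mathematically equivalent (supplementary
#' angles share their sine) and makes the mirrored pair bit-identical.
#'
#' @param i Within-block step index, `1 <= i <= n`.
#' @param n Block length.
#' @return Envelope value in `(0, 1]`.
#' @examples
#' envelope(2, 3)  # sin(pi/2) = 1
#' envelope(1, 3)  # sin(pi/4)
#' @export
envelope <- function(i, n) {
  if (any(i < 1L) || any(i > n))
    stop("within-block index i must lie in 1..n", call. = FALSE)
  sin(pmin(i, n + 1 - i) * pi / (n + 1))
}

#' Apply a perturbation block to a position
#'
#' Returns the perturbed position `u' = u + sin(i pi / (n + 1)) p` for the
#' block's current within-block index.
#'
#' @param u Numeric length-2 position vector.
#' @param block A `perturbation_block` from [draw_block()].
#' @param i Optional within-block index override; defaults to `block$i`.
#' @return The perturbed position `u'`, numeric length 2.
#' @examples
#' blk <- structure(list(p = c(0.1, -0.2), i = 2L, n = 3L),
#'                  class = "perturbation_block")
#' apply_perturbation(c(1, 1), blk)  # (1.1, 0.8)
#' @export
apply_perturbation <- function(u, block, i = block$i) {
  u + envelope(i, block$n) * block$p
}

#' @rdname simulate_search
#' @details `simulate_perturbed()` is an alias for [simulate_search()],
#'   named for symmetry with [simulate_noiseless()].
#' @export
simulate_perturbed <- function(params, schedules = NULL) {
  simulate_search(params, schedules)
}
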