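# Registry of published parameter sets.
#
# run2..run10: the nine parameter sets used to reconstruct the recorded
# Cataglyphis fortis searches (alpha, beta, s, b, f, n as printed).
# fig1-*/fig2-*/fig3-*: the parameter-sweep grids varying b, f and s
# around the common reference alpha=10, beta=3, s=0.12, b=0.2, n=3.
# fig7-*: the continuous-schedule presets (beta ramp 3 -> 1.8, optionally
# b ramp 0.08 -> -0.03, f = 0).
preset_table <- function() {
  base <- function(alpha = 10, beta = 3, s = 0.12, b = 0.2, f = 0.1,
                   n = 3L, schedules = NULL)
    list(alpha = alpha, beta = beta, s = s, b = b, f = f, n = n,
         schedules = schedules)
  runs <- list(
    run2  = base(beta = 3,   s = 0.08,  b = 0.3, f = 0.2, n = 3L),
    run3  = base(beta = 3,   s = 0.08,  b = 0.3, f = 0.2, n = 3L),
    run4  = base(beta = 3,   s = 0.1,   b = 0.3, f = 0.2, n = 3L),
    run5  = base(beta = 3.5, s = 0.15,  b = 0.3, f = 0.6, n = 2L),
    run6  = base(beta = 3.5, s = 0.15,  b = 0.2, f = 0.4, n = 2L),
    run7  = base(beta = 3,   s = 0.018, b = 0.3, f = 0.1, n = 3L),
    run8  = base(beta = 3,   s = 0.003, b = 0.3, f = 0.1, n = 3L),
    run9  = base(beta = 3,   s = 0.08,  b = 0.3, f = 0.2, n = 3L),
    run10 = base(beta = 3,   s = 0.08,  b = 0.3, f = 0.2, n = 3L)
  )
  sweeps <- list(
    # b sweep, f = 0 (left column) and f = 0.1
    `fig1-top-noiseless`    = base(b = 0.2,  f = 0),
    `fig1-top`              = base(b = 0.2,  f = 0.1),
    `fig1-centre-noiseless` = base(b = 0.02, f = 0),
    `fig1-centre`           = base(b = 0.02, f = 0.1),
    `fig1-bottom-noiseless` = base(b = 0,    f = 0),
    `fig1-bottom`           = base(b = 0,    f = 0.1),
    # f sweep
    `fig2-top`    = base(f = 0.1),
    `fig2-centre` = base(f = 0.04),
    `fig2-bottom` = base(f = 0.02),
    # s sweep
    `fig3-top-noiseless`    = base(s = 0.12, f = 0),
    `fig3-top`              = base(s = 0.12, f = 0.1),
    `fig3-centre-noiseless` = base(s = 0.07, f = 0),
    `fig3-centre`           = base(s = 0.07, f = 0.1),
    `fig3-bottom-noiseless` = base(s = 0.04, f = 0),
    `fig3-bottom`           = base(s = 0.04, f = 0.1)
  )
  ramps <- list(
    `fig7-left` = base(b = 0.08, f = 0,
                       schedules = list(param_schedule("beta", 3, 1.8))),
    `fig7-right` = base(b = 0.08, f = 0,
                        schedules = list(param_schedule("beta", 3, 1.8),
                                         param_schedule("b", 0.08, -0.03)))
  )
  c(runs, sweeps, ramps)
}

#' Named parameter presets
#'
#' `preset_names()` lists the available presets; `search_preset()` loads
#' one. `run2` to `run10` are the nine parameter sets used to reconstruct
#' recorded *Cataglyphis fortis* search runs; `fig1-*`, `fig2-*` and
#' `fig3-*` are the parameter-sweep grids varying the backward factor `b`,
#' the perturbation factor `f` and the step length `s`; `fig7-left` and
#' `fig7-right` carry the continuous schedules (a `beta` ramp from 3 to
#' 1.8, the right variant adding a `b` ramp from 0.08 to -0.03).
#'
#' @param name Preset name, see `preset_names()`.
#' @param ... Overrides passed on to the parameter object (e.g. `seed`,
#'   `n_steps`).
#' @return `search_preset()` returns a list with components `params` (a
#'   [search_params()] object) and `schedules` (a possibly empty list of
#'   [param_schedule()] objects). `preset_names()` returns a character
#'   vector.
#' @examples
#' preset_names()
#' search_preset("run5")$params
#' @export
search_preset <- function(name, ...) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'. Available presets: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  entry <- tab[[name]]
  schedules <- entry$schedules
  entry$schedules <- NULL
  params <- do.call(search_params, c(entry, list(...)))
  list(params = params, schedules = if (is.null(schedules)) list()
                                    else schedules)
}

#' @rdname search_preset
#' @export
preset_names <- function() {
  names(preset_table())
}
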