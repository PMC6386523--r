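#' Run configurations
#'
#' A run config bundles everything one simulation needs -- parameters (a
#' preset name or explicit values), lattice specification, initial
#' condition, optional clones, integration settings, seed and output path --
#' and is fully validated before any computation starts. Configs are
#' human-editable YAML files with nested sections; unknown keys are
#' rejected.
#'
#' Recognised sections and keys:
#' \preformatted{
#' preset: fig3            # or a nested `params:` section
#' lattice: {kind: hex_rect, n_cols: 20, n_rows: 20}   # chain_1d: n_cells;
#'                                                     # hex_disc: radius
#' ic: {kind: left_columns, columns: 3, amplitude: ~}  # angular_sector:
#'                                                     # theta1, theta2
#' clones:
#'   - {condition: egfr_ko, shape: rect, col_min: 12, col_max: 17,
#'      row_min: 5, row_max: 14}
#'   - {condition: ectopic_egfr, shape: disc, x: 10, y: 8.5, radius: 0}
#'   - {condition: notch_up, cells: [5, 6, 7]}
#' integration: {t_end: 25, dt: 0.02, record_every: 2.5}
#' seed: 1
#' out: path/to/output
#' }
#'
#' @param path Path to a YAML config file.
#' @return A validated `run_config` object.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("preset", "params", "lattice", "ic", "clones", "integration",
             "seed", "out")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "))

  params <- if (!is.null(raw$preset)) preset(raw$preset)
  else if (!is.null(raw$params)) params_from_list(raw$params)
  else model_params()

  lat_spec <- raw$lattice %||% list(kind = "chain_1d", n_cells = 100)
  lat_known <- c("kind", "n_cells", "n_cols", "n_rows", "radius")
  if (length(bad <- setdiff(names(lat_spec), lat_known)))
    stop("load_config: unknown lattice key(s): ", paste(bad, collapse = ", "))
  lattice <- switch(lat_spec$kind %||% "chain_1d",
    chain_1d = build_chain(lat_spec$n_cells %||% 100),
    hex_rect = build_hex_rect(lat_spec$n_cols %||% 20, lat_spec$n_rows %||% 20),
    hex_disc = build_hex_disc(lat_spec$radius %||% 15),
    stop("load_config: unknown lattice kind: ", lat_spec$kind))

  ic_spec <- raw$ic %||% list(kind = "left_columns", columns = 3)
  ic_known <- c("kind", "columns", "amplitude", "theta1", "theta2", "cells")
  if (length(bad <- setdiff(names(ic_spec), ic_known)))
    stop("load_config: unknown ic key(s): ", paste(bad, collapse = ", "))
  ic <- initial_condition(
    kind = ic_spec$kind %||% "left_columns",
    amplitude = ic_spec$amplitude,
    columns = ic_spec$columns %||% 3,
    theta = c(ic_spec$theta1 %||% (pi / 3), ic_spec$theta2 %||% (5 * pi / 3)),
    cells = ic_spec$cells)

  clones <- NULL
  if (!is.null(raw$clones)) {
    clones <- lapply(raw$clones, function(cs) {
      ck <- c("condition", "shape", "cells", "col_min", "col_max",
              "row_min", "row_max", "x", "y", "radius", "magnitude")
      if (length(bad <- setdiff(names(cs), ck)))
        stop("load_config: unknown clone key(s): ", paste(bad, collapse = ", "))
      cells <- if (!is.null(cs$cells)) as.integer(cs$cells)
      else switch(cs$shape %||% "rect",
        rect = clone_cells_rect(lattice, c(cs$col_min, cs$col_max),
                                c(cs$row_min, cs$row_max)),
        disc = clone_cells_disc(lattice, c(cs$x, cs$y), cs$radius),
        stop("load_config: unknown clone shape: ", cs$shape))
      clone_spec(cells, cs$condition, magnitude = cs$magnitude)
    })
  }

  intg <- raw$integration %||% list()
  if (length(bad <- setdiff(names(intg), c("t_end", "dt", "record_every"))))
    stop("load_config: unknown integration key(s): ",
         paste(bad, collapse = ", "))
  t_end <- intg$t_end %||% 25
  dt <- intg$dt %||% 0.02
  if (dt > max_stable_dt(params, lattice))
    stop("load_config: dt violates the stability bound")

  structure(list(params = params, lattice = lattice, ic = ic,
                 clones = clones, t_end = t_end, dt = dt,
                 record_every = intg$record_every %||% max(t_end / 50, dt),
                 seed = raw$seed, out = raw$out),
            class = "run_config")
}

#' Execute a run configuration
#'
#' @param config A `run_config` from [load_config()].
#' @return The resulting `pn_trajectory` (written to `config$out` when set).
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tr <- integrate_model(config$params, config$lattice, config$ic,
                        t_end = config$t_end, dt = config$dt,
                        record_every = config$record_every,
                        seed = config$seed, clone = config$clones)
  if (!is.null(config$out)) write_trajectory(tr, config$out)
  tr
}
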