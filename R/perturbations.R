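#' Clone specifications
#'
#' A clone is a set of cells carrying a named genetic perturbation, realised
#' as per-cell overrides of the integrated-model kinetics:
#'
#' * `"egfr_ko"` — knockout of EGFR signalling (`mu_E = 0` inside the clone).
#' * `"egfr_const"` — constitutively active EGFR signalling (the E production
#'   term is held at its maximal value: the `h(phi_E)` factor is clamped
#'   to 1).
#' * `"lsc_ko"` — L'sc knockout (`mu_L = 0`).
#' * `"lsc_const"` — constitutively active L'sc (L production term held
#'   maximal).
#' * `"notch_down"` — Notch downregulation (`beta = 0`).
#' * `"notch_up"` — Notch upregulation (additional constant N synthesis at
#'   rate `beta / 2`, or `magnitude` if given).
#' * `"notch_null"` — Notch-RNAi-like strong knockdown (`beta = 0` and
#'   `mu_N = 0`: complete loss of Notch production).
#' * `"ectopic_egfr"` — ectopic EGFR activation (same clamp as
#'   `"egfr_const"`; applied to single cells it nucleates a target-like
#'   transition wave in quiescent tissue).
#'
#' @param cells Integer cell indices forming the clone.
#' @param condition Perturbation name (see above).
#' @param magnitude Optional condition-specific value (currently: the extra
#'   Notch synthesis rate for `"notch_up"`).
#' @return An object of class `clone_spec`.
#' @export
clone_spec <- function(cells,
                       condition = c("egfr_ko", "egfr_const", "lsc_ko",
                                     "lsc_const", "notch_down", "notch_up",
                                     "notch_null", "ectopic_egfr"),
                       magnitude = NULL) {
  condition <- match.arg(condition)
  structure(list(cells = as.integer(cells), condition = condition,
                 magnitude = magnitude),
            class = "clone_spec")
}

#' @export
print.clone_spec <- function(x, ...) {
  cat(sprintf("<clone_spec> %s, %d cells\n", x$condition, length(x$cells)))
  invisible(x)
}

#' Select clone cells by geometry
#'
#' `clone_cells_rect` picks cells whose column index lies in `col_range` and
#' whose y coordinate lies within the rows `row_range` (inclusive, in row
#' units of the hexagonal lattice); `clone_cells_disc` picks cells within
#' `radius` of a centre point `c(x, y)`.
#'
#' @param lattice A `cell_lattice`.
#' @param col_range,row_range Integer ranges `c(lo, hi)` (0-based).
#' @param center Length-2 numeric centre `c(x, y)`.
#' @param radius Disc radius in lattice units.
#' @return Integer vector of cell indices.
#' @export
clone_cells_rect <- function(lattice, col_range, row_range) {
  stopifnot(inherits(lattice, "cell_lattice"))
  row <- round(lattice$coords$y / (sqrt(3) / 2))
  which(lattice$col >= col_range[1] & lattice$col <= col_range[2] &
          row >= row_range[1] & row <= row_range[2])
}

#' @rdname clone_cells_rect
#' @export
clone_cells_disc <- function(lattice, center, radius) {
  stopifnot(inherits(lattice, "cell_lattice"), length(center) == 2L)
  d <- sqrt((lattice$coords$x - center[1])^2 +
              (lattice$coords$y - center[2])^2)
  which(d <= radius + 1e-9)
}

#' Per-cell effective kinetics for clones
#'
#' Expands a `model_params` plus one or more [clone_spec()]s into per-cell
#' kinetic vectors (gain rates, basal Notch rate, extra Notch synthesis, and
#' clamp flags for constitutive E/L production). Cells outside every clone
#' keep the wildtype kinetics.
#'
#' @param params A `model_params` with `variant = "integrated"`.
#' @param clones A [clone_spec()] or list of them.
#' @param lattice The `cell_lattice` the clones live on.
#' @return A `cell_kinetics` object (named list of per-cell vectors).
#' @export
apply_clone <- function(params, clones, lattice) {
  stopifnot(inherits(params, "model_params"))
  if (params$variant != "integrated")
    stop("apply_clone: clones require the integrated variant")
  if (inherits(clones, "clone_spec")) clones <- list(clones)
  n <- lattice$n_cells
  kin <- list(mu_E = rep(params$mu_E, n), mu_L = rep(params$mu_L, n),
              mu_D = rep(params$mu_D, n), mu_N = rep(params$mu_N, n),
              beta = rep(params$beta, n), extra_N = numeric(n),
              clamp_E = numeric(n), clamp_L = numeric(n))
  for (cl in clones) {
    stopifnot(inherits(cl, "clone_spec"))
    idx <- cl$cells
    if (any(idx < 1L | idx > n))
      stop("apply_clone: clone cells outside lattice")
    switch(cl$condition,
      egfr_ko = { kin$mu_E[idx] <- 0 },
      egfr_const = ,
      ectopic_egfr = { kin$clamp_E[idx] <- 1 },
      lsc_ko = { kin$mu_L[idx] <- 0 },
      lsc_const = { kin$clamp_L[idx] <- 1 },
      notch_down = { kin$beta[idx] <- 0 },
      notch_up = {
        kin$extra_N[idx] <- kin$extra_N[idx] +
          (cl$magnitude %||% (params$beta / 2))
      },
      notch_null = { kin$beta[idx] <- 0; kin$mu_N[idx] <- 0 },
      stop("apply_clone: unknown condition ", cl$condition))
  }
  structure(kin, class = "cell_kinetics")
}

#' Classify a clone's wavefront phenotype against wildtype
#'
#' Compares the proneural wavefront within the tissue band spanned by the
#' clone between a perturbed and a wildtype run of the same protocol:
#'
#' * `"lost"` — the wildtype wave has passed the clone but almost no clone
#'   cell has undergone the NE-to-NB transition by the end of the perturbed
#'   trajectory (fraction of clone cells with `omega >= 0.5` below
#'   `lost_fraction`).
#' * `"advanced"` / `"delayed"` — the band-restricted front position at
#'   `t_eval` differs from wildtype by at least one lattice column.
#' * `"unchanged"` — otherwise.
#'
#' @param traj_wt,traj_clone Wildtype and perturbed `pn_trajectory` on the
#'   same lattice with the same initial condition.
#' @param clone The [clone_spec()] that was applied.
#' @param t_eval Evaluation time for the front comparison.
#' @param threshold Minimal front shift in columns (default 1).
#' @param lost_fraction Transition fraction below which the wave counts as
#'   lost within the clone.
#' @return Character scalar, one of `"lost"`, `"advanced"`, `"delayed"`,
#'   `"unchanged"`, with attributes `front_wt`, `front_clone`,
#'   `clone_transitioned`.
#' @export
classify_clone_phenotype <- function(traj_wt, traj_clone, clone,
                                     t_eval = max(traj_wt$times),
                                     threshold = 1, lost_fraction = 0.25) {
  stopifnot(inherits(traj_wt, "pn_trajectory"),
            inherits(traj_clone, "pn_trajectory"),
            inherits(clone, "clone_spec"))
  if (traj_wt$lattice$n_cells != traj_clone$lattice$n_cells)
    stop("classify_clone_phenotype: mismatched lattices")
  lattice <- traj_wt$lattice
  idx <- clone$cells
  # band: all cells sharing the clone's rows (y range)
  yr <- range(lattice$coords$y[idx])
  band <- which(lattice$coords$y >= yr[1] - 1e-6 &
                  lattice$coords$y <= yr[2] + 1e-6)

  end_wt <- traj_wt$states[[length(traj_wt$states)]]
  end_cl <- traj_clone$states[[length(traj_clone$states)]]
  frac_cl <- mean(end_cl$omega[idx] >= 0.5)
  frac_wt <- mean(end_wt$omega[idx] >= 0.5)

  f_wt <- wavefront_position(state_at(traj_wt, t_eval), lattice, cells = band)
  f_cl <- wavefront_position(state_at(traj_clone, t_eval), lattice,
                             cells = band)
  out <- if (frac_cl < lost_fraction && frac_wt >= 0.75) "lost"
  else if (is.finite(f_cl) && (!is.finite(f_wt) || f_cl - f_wt >= threshold))
    "advanced"
  else if (is.finite(f_wt) && (!is.finite(f_cl) || f_wt - f_cl >= threshold))
    "delayed"
  else "unchanged"
  structure(out, front_wt = f_wt, front_clone = f_cl,
            clone_transitioned = frac_cl)
}
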