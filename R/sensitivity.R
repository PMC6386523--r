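#' Morris elementary-effects screening plan
#'
#' One-at-a-time (elementary effects) screening: the parameter space is
#' discretised to a `levels`-point grid per parameter, and `trajectories`
#' random walks of `k + 1` points each (k = number of parameters) are drawn,
#' every consecutive pair differing in exactly one parameter by the grid
#' jump `delta` (a fraction of the normalised range). Each step yields one
#' elementary effect of the changed parameter; per parameter the screening
#' reports the signed mean effect `m` (positive and negative effects may
#' cancel), the mean absolute effect `m_star`, and the standard deviation
#' `sigma`, which signals nonlinearity and/or parameter interactions.
#'
#' @param parameters Data frame with columns `name`, `low`, `high` and
#'   optionally `log` (logical: sample the parameter on a log-spaced grid;
#'   sensible for kinetic rates).
#' @param levels Number of grid levels p (>= 2).
#' @param delta Grid jump as a fraction of the normalised range; the default
#'   `p / (2 (p - 1))` is the standard choice balancing the sampled levels.
#' @param trajectories Number of Morris trajectories r (>= 1).
#' @param seed RNG seed for the sampling.
#' @return An object of class `morris_plan`.
#' @export
morris_plan <- function(parameters, levels = 4L,
                        delta = levels / (2 * (levels - 1)),
                        trajectories = 50L, seed = 1L) {
  stopifnot(is.data.frame(parameters),
            all(c("name", "low", "high") %in% names(parameters)))
  if (is.null(parameters$log)) parameters$log <- FALSE
  if (any(parameters$low >= parameters$high))
    stop("morris_plan: each range needs low < high")
  if (any(parameters$log & parameters$low <= 0))
    stop("morris_plan: log-scaled parameters need low > 0")
  levels <- as.integer(levels)
  if (levels < 2L) stop("morris_plan: need levels >= 2")
  if (delta <= 0 || delta >= 1)
    stop("morris_plan: delta must lie in (0, 1)")
  # delta must connect grid points: a multiple of 1/(levels-1)
  if (abs(delta * (levels - 1) - round(delta * (levels - 1))) > 1e-9)
    stop("morris_plan: delta must be a multiple of 1/(levels - 1)")
  if (trajectories < 1L) stop("morris_plan: need trajectories >= 1")
  structure(list(parameters = parameters, levels = levels, delta = delta,
                 trajectories = as.integer(trajectories),
                 seed = as.integer(seed)),
            class = "morris_plan")
}

#' @export
print.morris_plan <- function(x, ...) {
  cat(sprintf("<morris_plan> %d parameters, p = %d levels, delta = %.3g, r = %d\n",
              nrow(x$parameters), x$levels, x$delta, x$trajectories))
  invisible(x)
}

# normalised [0,1] -> native units
morris_denorm <- function(u, plan) {
  p <- plan$parameters
  ifelse(p$log, p$low * (p$high / p$low)^u, p$low + u * (p$high - p$low))
}

#' Draw Morris trajectories
#'
#' Each trajectory starts from a random grid point and visits the k
#' parameters in random order, stepping each once by `+delta` or `-delta`
#' (direction random, flipped when the step would leave `[0, 1]`).
#'
#' @param plan A [morris_plan()].
#' @return List of `r` matrices, each `(k + 1) x k` in native units, with
#'   attribute `normalized` (the same points in `[0, 1]` coordinates).
#' @export
morris_sample <- function(plan) {
  stopifnot(inherits(plan, "morris_plan"))
  set.seed(plan$seed)
  k <- nrow(plan$parameters)
  grid <- seq(0, 1, length.out = plan$levels)
  out <- vector("list", plan$trajectories)
  for (r in seq_len(plan$trajectories)) {
    u <- matrix(NA_real_, k + 1L, k)
    u[1L, ] <- sample(grid, k, replace = TRUE)
    order_k <- sample.int(k)
    for (step in seq_len(k)) {
      j <- order_k[step]
      u[step + 1L, ] <- u[step, ]
      s <- sample(c(-1, 1), 1L)
      cand <- u[step, j] + s * plan$delta
      if (cand < -1e-12 || cand > 1 + 1e-12) cand <- u[step, j] - s * plan$delta
      if (cand < -1e-12 || cand > 1 + 1e-12)
        stop("morris_sample: delta incompatible with grid")
      u[step + 1L, j] <- min(max(cand, 0), 1)
    }
    x <- t(apply(u, 1L, morris_denorm, plan = plan))
    colnames(x) <- plan$parameters$name
    attr(x, "normalized") <- u
    out[[r]] <- x
  }
  out
}

#' Elementary effects from trajectory outputs
#'
#' For each within-trajectory step that changes parameter i, the elementary
#' effect is `(y_after - y_before) / (x_after - x_before)` in the
#' parameter's native units. Non-finite outputs are excluded and counted.
#'
#' @param points List of trajectory point matrices (from [morris_sample()]).
#' @param outputs List of numeric vectors, one output value per point.
#' @param plan The [morris_plan()].
#' @return Named list (one entry per parameter) of effect samples, with
#'   attribute `n_excluded`.
#' @export
elementary_effects <- function(points, outputs, plan) {
  stopifnot(length(points) == length(outputs))
  k <- nrow(plan$parameters)
  eff <- stats::setNames(rep(list(numeric(0)), k), plan$parameters$name)
  n_excluded <- 0L
  for (r in seq_along(points)) {
    x <- points[[r]]
    y <- outputs[[r]]
    stopifnot(length(y) == nrow(x))
    for (step in seq_len(nrow(x) - 1L)) {
      dx <- x[step + 1L, ] - x[step, ]
      j <- which(abs(dx) > 1e-12)
      if (length(j) != 1L)
        stop("elementary_effects: step must change exactly one parameter")
      if (!is.finite(y[step]) || !is.finite(y[step + 1L])) {
        n_excluded <- n_excluded + 1L
        next
      }
      eff[[j]] <- c(eff[[j]], (y[step + 1L] - y[step]) / dx[j])
    }
  }
  attr(eff, "n_excluded") <- n_excluded
  eff
}

#' Morris indices from elementary-effect samples
#'
#' @param effects Named list of per-parameter effect samples
#'   (from [elementary_effects()]).
#' @return Data frame of class `morris_result` with columns `parameter`,
#'   `m` (signed mean), `m_star` (mean absolute), `sigma` (sd),
#'   `n_effects`.
#' @export
morris_indices <- function(effects) {
  if (any(lengths(effects) < 2L))
    stop("morris_indices: need >= 2 effects per parameter")
  res <- data.frame(
    parameter = names(effects),
    m = vapply(effects, mean, numeric(1)),
    m_star = vapply(effects, function(e) mean(abs(e)), numeric(1)),
    sigma = vapply(effects, stats::sd, numeric(1)),
    n_effects = lengths(effects),
    row.names = NULL
  )
  class(res) <- c("morris_result", "data.frame")
  res
}

#' Default sensitivity protocol
#'
#' Defines how each sampled parameter point is turned into the two outputs
#' of interest: the integrated model is run on a 1D chain from a left-edge
#' excitation, and wave speed (cells/time) and transition-zone width (cells)
#' are measured. Runs without a measurable wave (no front, or a poor linear
#' fit) are flagged as degenerate (`NA`), to be excluded with a report.
#'
#' @param n_cells Chain length.
#' @param t_end,dt Integration settings.
#' @param base A `model_params` supplying all non-screened parameters.
#' @param min_r2 Minimal front-fit R-squared for a run to count as a wave.
#' @return A protocol object (list with an `evaluate(values)` function).
#' @export
sensitivity_protocol <- function(n_cells = 70, t_end = 45, dt = 0.02,
                                 base = model_params(), min_r2 = 0.9) {
  lattice <- build_chain(n_cells)
  ic <- initial_condition("left_columns", columns = 3)
  evaluate <- function(values) {
    args <- c(list(variant = "integrated"), as.list(values))
    args$hill <- base$hill
    for (nm in setdiff(c("eta", "mu_E", "k_E", "mu_L", "k_L", "mu_D", "k_D",
                         "mu_N", "k_N", "beta", "sigma_N", "k_Omega"),
                       names(values)))
      args[[nm]] <- base[[nm]]
    p <- do.call(model_params, args)
    this_dt <- min(dt, 0.9 * max_stable_dt(p, lattice))
    tr <- integrate_model(p, lattice, ic, t_end = t_end, dt = this_dt,
                          record_every = 1)
    ws <- tryCatch(wave_speed(tr), error = function(e) NULL)
    # a pinned or stalling excitation is not a wave: both outputs degenerate
    speed <- if (is.null(ws) || ws$r2 < min_r2 || ws$speed < 0.02)
      NA_real_ else ws$speed
    width <- if (is.na(speed)) NA_real_ else transition_zone_width(tr)
    c(speed = speed, width = width)
  }
  structure(list(n_cells = n_cells, t_end = t_end, dt = dt, base = base,
                 evaluate = evaluate),
            class = "sensitivity_protocol")
}

#' Default Morris screening ranges
#'
#' The screened parameters are the kinetic rates of EGFR signalling, L'sc
#' expression and Delta-Notch signalling (`mu_i`, `k_i` for i = E, L, D, N),
#' the EGFR diffusion constant `eta` and the basal Notch gain rate `beta`.
#' Ranges default to +/- 20% around the reference values, screened on a
#' log-spaced grid (rates are scale parameters). Wider spans push a large
#' share of sampled corners past the propagation-failure boundary of the
#' excitable medium (e.g. `mu_E / k_E` below the bistability threshold),
#' starving the elementary-effect estimates; the span is configurable.
#'
#' @param base A `model_params` providing the reference values.
#' @param span Fractional half-width of the ranges (default 0.2).
#' @return Data frame suitable for [morris_plan()].
#' @export
default_sensitivity_ranges <- function(base = model_params(), span = 0.2) {
  nm <- c("eta", "mu_E", "k_E", "mu_L", "k_L", "mu_D", "k_D",
          "mu_N", "k_N", "beta")
  ref <- unlist(base[nm])
  data.frame(name = nm, low = ref * (1 - span), high = ref * (1 + span),
             log = TRUE, row.names = NULL)
}

#' Run the Morris screening of wave speed and zone width
#'
#' Samples the plan, evaluates the simulation protocol at every point, and
#' assembles Morris indices per output. Degenerate runs (no measurable wave:
#' the excitation pins, or the whole tissue ignites) are excluded from the
#' effects with a count in the result's `n_degenerate` attribute. Because
#' the travelling-wave regime occupies a finite band of parameter space,
#' some sampled corners are always degenerate; if after the planned
#' trajectories any parameter has fewer than `min_effects` valid effects,
#' additional trajectories (drawn deterministically from the same seed, up
#' to `max_extra`) are evaluated until every parameter is covered.
#'
#' @param plan A [morris_plan()].
#' @param protocol A [sensitivity_protocol()].
#' @param min_effects Minimal number of valid elementary effects required
#'   per parameter and output.
#' @param max_extra Maximal number of top-up trajectories (default: at
#'   least 10).
#' @return Data frame of class `morris_result` with an additional `output`
#'   column (`"speed"`, `"width"`); attributes `n_degenerate`, `n_runs`,
#'   `n_trajectories`.
#' @export
run_sensitivity <- function(plan, protocol = sensitivity_protocol(),
                            min_effects = 2L,
                            max_extra = max(plan$trajectories, 10L)) {
  stopifnot(inherits(plan, "morris_plan"),
            inherits(protocol, "sensitivity_protocol"))
  big <- plan
  big$trajectories <- plan$trajectories + max_extra
  all_points <- morris_sample(big)
  outs <- list()
  n_use <- plan$trajectories
  evaluate_up_to <- function(n) {
    for (r in seq_len(n)) {
      if (length(outs) < r || is.null(outs[[r]]))
        outs[[r]] <<- t(apply(all_points[[r]], 1L, protocol$evaluate))
    }
  }
  effects_for <- function(what, n) {
    ys <- lapply(outs[seq_len(n)], function(m) m[, what])
    elementary_effects(all_points[seq_len(n)], ys, plan)
  }
  evaluate_up_to(n_use)
  repeat {
    covered <- all(vapply(c("speed", "width"), function(what)
      all(lengths(effects_for(what, n_use)) >= min_effects), logical(1)))
    if (covered || n_use >= big$trajectories) break
    n_use <- n_use + 1L
    evaluate_up_to(n_use)
  }
  res <- list()
  n_degenerate <- 0L
  for (what in c("speed", "width")) {
    eff <- effects_for(what, n_use)
    n_degenerate <- max(n_degenerate, attr(eff, "n_excluded"))
    if (any(lengths(eff) < min_effects))
      stop("run_sensitivity: parameter(s) without enough valid effects ",
           "for output ", what, " (all sampled neighbourhoods degenerate)")
    idx <- morris_indices(eff)
    idx$output <- what
    res[[what]] <- idx
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("morris_result", "data.frame")
  attr(out, "n_degenerate") <- n_degenerate
  attr(out, "n_runs") <- n_use * (nrow(plan$parameters) + 1L)
  attr(out, "n_trajectories") <- n_use
  out
}
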