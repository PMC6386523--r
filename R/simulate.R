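#' Initial-condition specifications
#'
#' Describes where the tissue starts with elevated EGFR signalling:
#' * `"left_columns"` — the first `columns` cell columns at the left tissue
#'   boundary (the standard wave-initiation protocol on chains and patches).
#' * `"angular_sector"` — the outer boundary cells of a disc whose polar
#'   angle lies in `[theta[1], theta[2]]` (measured counter-clockwise from
#'   the +x axis).
#' * `"cell_set"` — an explicit list of cell indices.
#' * `"uniform"` — every cell.
#'
#' If `amplitude` is `NULL` it defaults, when the state is built, to the
#' upper stable root of the E kinetics ([e_upper_root()]), guaranteeing a
#' super-threshold excitation.
#'
#' @param kind Selector kind.
#' @param amplitude Initial `phi_E` level on selected cells (>= 0), or `NULL`.
#' @param columns Number of left-boundary columns (for `"left_columns"`).
#' @param theta Length-2 angle interval in `[0, 2*pi]`
#'   (for `"angular_sector"`).
#' @param cells Integer cell indices (for `"cell_set"`).
#' @return An object of class `initial_condition`.
#' @export
initial_condition <- function(kind = c("left_columns", "angular_sector",
                                       "cell_set", "uniform"),
                              amplitude = NULL, columns = 3,
                              theta = c(pi / 3, 5 * pi / 3), cells = NULL) {
  kind <- match.arg(kind)
  if (!is.null(amplitude)) {
    stopifnot(is.numeric(amplitude), length(amplitude) == 1L)
    if (amplitude < 0) stop("initial_condition: amplitude must be >= 0")
  }
  if (kind == "angular_sector") {
    stopifnot(length(theta) == 2L)
    if (any(theta < 0 | theta > 2 * pi))
      stop("initial_condition: angles must lie in [0, 2*pi]")
  }
  if (kind == "cell_set" && is.null(cells))
    stop("initial_condition: kind 'cell_set' needs `cells`")
  structure(list(kind = kind, amplitude = amplitude,
                 columns = as.integer(columns), theta = theta,
                 cells = if (!is.null(cells)) as.integer(cells)),
            class = "initial_condition")
}

#' Build the initial tissue state from an initial condition
#'
#' Sets `phi_E = amplitude` on the selected cells and 0 elsewhere; all other
#' fields start at 0 and every cell is neuroepithelial (`omega = 0`).
#'
#' @param ic An [initial_condition()].
#' @param lattice A `cell_lattice`.
#' @param params Optional `model_params`, used to resolve a `NULL` amplitude
#'   to the upper stable root of the E kinetics.
#' @return A `tissue_state`: named list of per-cell numeric vectors `phi_E`,
#'   `phi_L`, `phi_D`, `phi_N`, `omega`.
#' @export
apply_initial_condition <- function(ic, lattice, params = NULL) {
  stopifnot(inherits(ic, "initial_condition"), inherits(lattice, "cell_lattice"))
  n <- lattice$n_cells
  amp <- ic$amplitude
  if (is.null(amp))
    amp <- if (!is.null(params)) e_upper_root(params) else 4
  sel <- switch(ic$kind,
    uniform = seq_len(n),
    left_columns = which(lattice$col < ic$columns),
    cell_set = {
      if (any(ic$cells < 1L | ic$cells > n))
        stop("apply_initial_condition: cell indices outside lattice")
      ic$cells
    },
    angular_sector = {
      if (lattice$kind != "hex_disc")
        stop("apply_initial_condition: angular sector needs a hex_disc lattice")
      boundary <- lattice$degree < 6L
      which(boundary & lattice$angle >= ic$theta[1] &
              lattice$angle <= ic$theta[2])
    })
  phi_E <- numeric(n)
  phi_E[sel] <- amp
  structure(list(phi_E = phi_E, phi_L = numeric(n), phi_D = numeric(n),
                 phi_N = numeric(n), omega = numeric(n)),
            class = "tissue_state")
}

max_stable_dt <- function(params, lattice) {
  k_max <- switch(params$variant,
    e_only = params$k_E,
    e_l = max(params$k_E, params$k_L),
    integrated = max(params$k_E, params$k_L, params$k_D, params$k_N,
                     params$k_Omega))
  0.2 / (k_max + params$eta * lattice$lap_coef * max(lattice$degree))
}

#' Time-integrate a model on a lattice
#'
#' Explicit forward-Euler stepping of the chosen model variant; with
#' `gamma > 0` the scheme is Euler-Maruyama with independent Gaussian noise
#' increments added to each phi-field (not to omega), after which fields are
#' clipped at zero. Noise increments scale as
#' `gamma * sqrt(phi) * sqrt(dt)` (`noise = "demographic"`, the chemical
#' Langevin form, default) or `gamma * sqrt(dt)` (`noise = "additive"`).
#' The step size is validated against the explicit-scheme stability bound
#' `dt <= 0.2 / (max decay rate + eta * c * max degree)`.
#'
#' @param params A `model_params`.
#' @param lattice A `cell_lattice`.
#' @param ic An [initial_condition()], or a ready-made `tissue_state`.
#' @param t_end Final time (> 0).
#' @param dt Time step.
#' @param record_every Recording cadence (decoupled from `dt`).
#' @param seed Integer RNG seed; required when `gamma > 0`, ignored (and a
#'   deterministic path produced) when `gamma == 0`.
#' @param clone Optional [clone_spec()] (or list of them) applied as per-cell
#'   kinetic overrides; integrated variant only.
#' @param noise Noise increment scaling, see above.
#' @param noise_fields Which phi-fields receive noise. The default for the
#'   integrated variant is the Delta equation (`"phi_D"`): fluctuations in
#'   ligand presentation are what seed (or fail to seed) lateral-inhibition
#'   patterning, and this placement preserves the integrity of the
#'   propagating EGFR excitation at the documented noise strength. For the
#'   E-only and E+L variants all present fields receive noise.
#' @return A `pn_trajectory`: list with `times`, `states` (one
#'   `tissue_state` per time), `params`, `lattice`, `seed`, `clone`, `dt`.
#' @export
integrate_model <- function(params, lattice, ic, t_end, dt = 0.01,
                            record_every = 0.5, seed = NULL, clone = NULL,
                            noise = c("additive", "demographic"),
                            noise_fields = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(lattice, "cell_lattice"))
  noise <- match.arg(noise)
  if (is.null(noise_fields))
    noise_fields <- switch(params$variant,
      e_only = "phi_E",
      e_l = c("phi_E", "phi_L"),
      integrated = "phi_D")
  allowed <- c("phi_E", "phi_L", "phi_D", "phi_N")
  if (length(bad <- setdiff(noise_fields, allowed)))
    stop("integrate_model: unknown noise field(s): ", paste(bad, collapse = ", "))
  if (t_end <= 0) stop("integrate_model: t_end must be > 0")
  dt_max <- max_stable_dt(params, lattice)
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("integrate_model: dt = %g exceeds stability bound %g",
                 dt, dt_max))
  stochastic <- params$gamma > 0
  if (stochastic && is.null(seed))
    stop("integrate_model: gamma > 0 requires a seed")
  if (stochastic) set.seed(as.integer(seed))

  state <- if (inherits(ic, "initial_condition"))
    apply_initial_condition(ic, lattice, params) else ic
  stopifnot(length(state$phi_E) == lattice$n_cells)

  kin <- NULL
  if (!is.null(clone)) {
    if (params$variant != "integrated")
      stop("integrate_model: clones require the integrated variant")
    if (inherits(clone, "clone_spec")) clone <- list(clone)
    kin <- apply_clone(params, clone, lattice)
  }

  n <- lattice$n_cells
  Lmat <- params$eta * laplacian_matrix(lattice)
  Mmat <- if (params$variant == "integrated") neighbor_mean_matrix(lattice)
  E <- state$phi_E; L <- state$phi_L; D <- state$phi_D
  N <- state$phi_N; Om <- state$omega

  n_steps <- ceiling(t_end / dt - 1e-9)
  stride <- max(1L, as.integer(round(record_every / dt)))
  n_rec <- length(seq(0L, n_steps, by = stride))
  if (n_steps %% stride != 0L) n_rec <- n_rec + 1L
  times <- numeric(0)
  states <- vector("list", 0)
  rec <- function(t) {
    times[[length(times) + 1L]] <<- t
    states[[length(states) + 1L]] <<-
      structure(list(phi_E = E, phi_L = L, phi_D = D, phi_N = N, omega = Om),
                class = "tissue_state")
  }
  rec(0)
  sdt <- sqrt(dt)
  gam <- params$gamma
  noise_inc <- if (noise == "demographic")
    function(phi) gam * sqrt(pmax(phi, 0)) * sdt * stats::rnorm(n)
  else
    function(phi) gam * sdt * stats::rnorm(n)
  nf <- c(E = "phi_E" %in% noise_fields, L = "phi_L" %in% noise_fields,
          D = "phi_D" %in% noise_fields, N = "phi_N" %in% noise_fields)

  for (s in seq_len(n_steps)) {
    diffE <- as.numeric(Lmat %*% E)
    if (params$variant == "e_only") {
      hE <- hill(E, params$hill$e_self)
      E <- E + dt * (diffE + params$mu_E * hE - params$k_E * E)
      if (stochastic && nf[["E"]]) E <- E + noise_inc(E)
      E[E < 0] <- 0
    } else if (params$variant == "e_l") {
      hE <- hill(E, params$hill$e_self)
      hL <- hill(L, params$hill$l_on_e)
      dE <- diffE + params$mu_E * hE * (1 - hL) - params$k_E * E
      dL <- params$mu_L * hE - params$k_L * L
      E <- E + dt * dE
      L <- L + dt * dL
      if (stochastic) {
        if (nf[["E"]]) E <- E + noise_inc(E)
        if (nf[["L"]]) L <- L + noise_inc(L)
      }
      E[E < 0] <- 0; L[L < 0] <- 0
    } else {
      Dbar <- as.numeric(Mmat %*% D)
      r <- integrated_local_rates(E, L, D, N, Om, Dbar, params, kin)
      E <- E + dt * (diffE + r$phi_E)
      L <- L + dt * r$phi_L
      D <- D + dt * r$phi_D
      N <- N + dt * r$phi_N
      Om <- Om + dt * r$omega
      if (stochastic) {
        if (nf[["E"]]) E <- E + noise_inc(E)
        if (nf[["L"]]) L <- L + noise_inc(L)
        if (nf[["D"]]) D <- D + noise_inc(D)
        if (nf[["N"]]) N <- N + noise_inc(N)
      }
      E[E < 0] <- 0; L[L < 0] <- 0; D[D < 0] <- 0; N[N < 0] <- 0
      Om[Om > 1] <- 1
    }
    if (s %% stride == 0L || s == n_steps) rec(s * dt)
  }

  structure(list(times = unlist(times), states = states, params = params,
                 lattice = lattice, seed = seed, clone = clone, dt = dt,
                 noise = noise, noise_fields = noise_fields),
            class = "pn_trajectory")
}

#' @export
print.pn_trajectory <- function(x, ...) {
  cat(sprintf(
    "<pn_trajectory> %s model, %d cells, %d snapshots over t = [%g, %g]\n",
    x$params$variant, x$lattice$n_cells, length(x$times),
    min(x$times), max(x$times)))
  invisible(x)
}

#' Recorded state nearest a given time
#'
#' @param traj A `pn_trajectory`.
#' @param time Requested time; the nearest recorded snapshot is returned.
#' @return A `tissue_state`.
#' @export
state_at <- function(traj, time) {
  stopifnot(inherits(traj, "pn_trajectory"))
  traj$states[[which.min(abs(traj$times - time))]]
}

#' Flat per-snapshot table of a trajectory
#'
#' @param traj A `pn_trajectory`.
#' @param time Snapshot time (nearest recorded state).
#' @return Data frame with columns `cell_id`, `x`, `y`, `E`, `L`, `D`, `N`,
#'   `Omega`.
#' @export
snapshot_table <- function(traj, time = max(traj$times)) {
  s <- state_at(traj, time)
  data.frame(cell_id = seq_len(traj$lattice$n_cells),
             x = traj$lattice$coords$x, y = traj$lattice$coords$y,
             E = s$phi_E, L = s$phi_L, D = s$phi_D, N = s$phi_N,
             Omega = s$omega)
}

#' Write / read a trajectory as a plain-text container
#'
#' Lays the trajectory out as a directory: `times.csv`, one time-by-cell CSV
#' matrix per field under `fields/` (`E`, `L`, `D`, `N`, `Omega`), the
#' lattice tables under `lattice/`, and `meta.yaml` holding parameters, seed
#' and step size.
#'
#' @param traj A `pn_trajectory`.
#' @param path Output directory.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory` a
#'   `pn_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pn_trajectory"))
  dir.create(file.path(path, "fields"), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(time = traj$times),
                   file.path(path, "times.csv"), row.names = FALSE)
  fields <- c(E = "phi_E", L = "phi_L", D = "phi_D", N = "phi_N",
              Omega = "omega")
  for (nm in names(fields)) {
    m <- do.call(rbind, lapply(traj$states, `[[`, fields[[nm]]))
    utils::write.csv(m, file.path(path, "fields", paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  write_lattice(traj$lattice, file.path(path, "lattice"))
  meta <- list(params = params_to_list(traj$params),
               seed = traj$seed, dt = traj$dt, noise = traj$noise)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  times <- utils::read.csv(file.path(path, "times.csv"))$time
  lattice <- read_lattice(file.path(path, "lattice"))
  fields <- c(E = "phi_E", L = "phi_L", D = "phi_D", N = "phi_N",
              Omega = "omega")
  mats <- lapply(names(fields), function(nm)
    as.matrix(utils::read.csv(file.path(path, "fields", paste0(nm, ".csv")))))
  names(mats) <- fields
  states <- lapply(seq_along(times), function(i) {
    structure(lapply(mats, function(m) unname(m[i, ])), class = "tissue_state")
  })
  structure(list(times = times, states = states,
                 params = params_from_list(meta$params),
                 lattice = lattice, seed = meta$seed, clone = NULL,
                 dt = meta$dt, noise = meta$noise),
            class = "pn_trajectory")
}
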