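#' Per-cell dynamical fields
#'
#' Bundles the local state of one cell (or, vectorised, of every cell):
#' signalling/expression levels `phi_E`, `phi_L`, `phi_D`, `phi_N` (all
#' non-negative) and the cell-state variable `omega` in `[0, 1]`
#' (0 = neuroepithelial cell, 1 = neuroblast).
#'
#' @param phi_E,phi_L,phi_D,phi_N Non-negative numeric vectors.
#' @param omega Numeric vector in `[0, 1]`.
#' @return An object of class `cell_fields`.
#' @export
cell_fields <- function(phi_E = 0, phi_L = 0, phi_D = 0, phi_N = 0,
                        omega = 0) {
  n <- max(length(phi_E), length(phi_L), length(phi_D), length(phi_N),
           length(omega))
  f <- list(phi_E = rep_len(as.numeric(phi_E), n),
            phi_L = rep_len(as.numeric(phi_L), n),
            phi_D = rep_len(as.numeric(phi_D), n),
            phi_N = rep_len(as.numeric(phi_N), n),
            omega = rep_len(as.numeric(omega), n))
  if (any(f$phi_E < 0 | f$phi_L < 0 | f$phi_D < 0 | f$phi_N < 0))
    stop("cell_fields: phi fields must be non-negative")
  if (any(f$omega < 0 | f$omega > 1))
    stop("cell_fields: omega must lie in [0, 1]")
  structure(f, class = "cell_fields")
}

#' Reaction kinetics of the single-component EGFR model
#'
#' The non-diffusive part of the E-only model,
#' \eqn{\mu_E h(\phi_E) - k_E \phi_E}: autocatalytic production through the
#' EGFR/Rhomboid/Spitz positive feedback loop balanced by first-order decay.
#' At the reference parameters (mu/k = 4, n = 3, a = 1) the kinetics is
#' bistable, with stable rest and elevated-signalling states separated by an
#' unstable threshold.
#'
#' @param fields A [cell_fields()] object (only `phi_E` is consulted).
#' @param params A `model_params` with `variant = "e_only"`.
#' @return Numeric vector `d phi_E / dt` (reaction part).
#' @export
reaction_E <- function(fields, params) {
  stopifnot(inherits(fields, "cell_fields"), inherits(params, "model_params"))
  if (params$variant != "e_only")
    stop("reaction_E: params variant must be 'e_only'")
  params$mu_E * hill(fields$phi_E, params$hill$e_self) -
    params$k_E * fields$phi_E
}

#' Reaction kinetics of the EGFR + L'sc excitable model
#'
#' Non-diffusive parts of the two-component model: EGFR gain is shut down by
#' L'sc (the consequence of the fate transition it drives), and L'sc is
#' activated by EGFR signalling:
#' \deqn{d\phi_E/dt = \mu_E h(\phi_E)[1 - h(\phi_L)] - k_E \phi_E,\quad
#'       d\phi_L/dt = \mu_L h(\phi_E) - k_L \phi_L.}
#' This indirect negative feedback converts the bistable E kinetics into an
#' excitable one: the rest state (0, 0) is the only non-negative fixed point,
#' and a super-threshold E perturbation produces a transient pulse.
#'
#' @param fields A [cell_fields()] object (`phi_E`, `phi_L` consulted).
#' @param params A `model_params` with `variant = "e_l"`.
#' @return List with numeric components `phi_E`, `phi_L` (reaction rates).
#' @export
reaction_EL <- function(fields, params) {
  stopifnot(inherits(fields, "cell_fields"), inherits(params, "model_params"))
  if (params$variant != "e_l")
    stop("reaction_EL: params variant must be 'e_l'")
  hE <- hill(fields$phi_E, params$hill$e_self)
  hL <- hill(fields$phi_L, params$hill$l_on_e)
  list(phi_E = params$mu_E * hE * (1 - hL) - params$k_E * fields$phi_E,
       phi_L = params$mu_L * hE - params$k_L * fields$phi_L)
}

# Vectorised kinetics of the integrated model. E, L, D, N, Om and Dbar are
# numeric vectors over cells; `kin` (optional) carries per-cell overrides
# produced by apply_clone(): vectors mu_E, mu_L, mu_D, mu_N, beta, extra_N
# and 0/1 clamp_E, clamp_L. Returns the five local rates (diffusion of E is
# added by the integrator).
integrated_local_rates <- function(E, L, D, N, Om, Dbar, p, kin = NULL) {
  hs <- p$hill
  hE  <- hill(E, hs$e_self)
  hLE <- hill(L, hs$l_on_e)
  hNE <- hill(N, hs$n_on_e)
  hEL <- hill(E, hs$e_on_l)
  hNL <- hill(N, hs$n_on_l)
  hED <- hill(E, hs$e_on_d)
  hND <- hill(N, hs$n_on_d)
  hDt <- hill(Dbar, hs$d_trans)
  hDc <- hill(D, hs$d_cis)
  hLN <- hill(L, hs$l_on_n)
  hLO <- hill(L, hs$l_on_omega)
  hEO <- hill(E, hs$e_on_omega)
  hNO <- hill(N, hs$n_on_omega)

  if (is.null(kin)) {
    mu_E <- p$mu_E; mu_L <- p$mu_L; mu_D <- p$mu_D; mu_N <- p$mu_N
    beta <- p$beta; extra_N <- 0
    actE <- hE
    actL <- hEL * (1 - hNL)
  } else {
    mu_E <- kin$mu_E; mu_L <- kin$mu_L; mu_D <- kin$mu_D; mu_N <- kin$mu_N
    beta <- kin$beta; extra_N <- kin$extra_N
    actE <- ifelse(kin$clamp_E > 0, 1, hE)
    actL <- ifelse(kin$clamp_L > 0, 1, hEL * (1 - hNL))
  }

  ne <- 1 - Om  # neuroepithelial occupancy gates transition-zone signalling
  prodE <- if (identical(p$notch_E, "multiplicative"))
    mu_E * actE * (1 - hLE) * (1 + p$sigma_N * hNE)
  else
    mu_E * actE * (1 - hLE) + p$sigma_N * hNE
  list(
    phi_E = ne * prodE - p$k_E * E,
    phi_L = ne * mu_L * actL - p$k_L * L,
    phi_D = ne * mu_D * hED * (1 - hND) - p$k_D * D,
    phi_N = (beta + mu_N * hDt) * (1 - hDc) * (1 - hLN) + extra_N - p$k_N * N,
    omega = p$k_Omega * ne * (hLO + hEO * (1 - hNO))
  )
}

#' Reaction kinetics of the integrated E/L/D/N/Omega model
#'
#' Local (per-cell) rates of the integrated model. Every regulatory arrow of
#' the network is realised by one Hill factor (see [model_params()]):
#' \deqn{d\phi_E/dt = (1-\Omega)[\mu_E h(\phi_E)(1 - h(\phi_L)) +
#'       \sigma_N h(\phi_N)] - k_E \phi_E}
#' \deqn{d\phi_L/dt = (1-\Omega)\,\mu_L h(\phi_E)(1 - h(\phi_N)) - k_L \phi_L}
#' \deqn{d\phi_D/dt = (1-\Omega)\,\mu_D h(\phi_E)(1 - h(\phi_N)) - k_D \phi_D}
#' \deqn{d\phi_N/dt = [\beta + \mu_N h(\bar\phi_D)](1 - h(\phi_D))
#'       (1 - h(\phi_L)) - k_N \phi_N}
#' \deqn{d\Omega/dt = k_\Omega (1-\Omega)[h(\phi_L) +
#'       h(\phi_E)(1 - h(\phi_N))]}
#' where \eqn{\bar\phi_D} is the mean Delta level over the cell's lattice
#' neighbours (trans-activation), \eqn{1 - h(\phi_D)} in the N equation is
#' cis-inhibition by the cell's own Delta, and the neuroepithelial occupancy
#' \eqn{(1-\Omega)} shuts down transition-zone signalling in completed
#' neuroblasts. The Omega rate is non-negative: the fate transition is
#' irreversible, driven by L'sc and by EGFR signalling in the absence of
#' Notch. The diffusion term \eqn{\eta \nabla^2 \phi_E} is added by the
#' integrator on a lattice.
#'
#' @param fields A [cell_fields()] object.
#' @param neighbor_mean_D Non-negative numeric: mean Delta over the cell's
#'   neighbours (vectorised over cells).
#' @param params A `model_params` with `variant = "integrated"`.
#' @return List of numeric rates `phi_E`, `phi_L`, `phi_D`, `phi_N`, `omega`.
#' @export
reaction_integrated <- function(fields, neighbor_mean_D, params) {
  stopifnot(inherits(fields, "cell_fields"), inherits(params, "model_params"))
  if (params$variant != "integrated")
    stop("reaction_integrated: params variant must be 'integrated'")
  if (any(neighbor_mean_D < 0))
    stop("reaction_integrated: negative neighbor_mean_D")
  integrated_local_rates(fields$phi_E, fields$phi_L, fields$phi_D,
                         fields$phi_N, fields$omega, neighbor_mean_D, params)
}

#' Fixed points of the single-component E kinetics
#'
#' Scans \eqn{\mu_E h(\phi_E) - k_E \phi_E} for sign changes on a fine grid
#' over `[0, upper]` and polishes each bracketed root with [stats::uniroot()];
#' classifies each root as stable (negative rate derivative) or unstable. At
#' mu/k = 4, n = 3, a = 1 the kinetics is bistable: roots at 0 and about
#' 3.935 (stable) separated by an unstable threshold near 0.537.
#'
#' @param params A `model_params` (the `e_self` Hill spec, `mu_E`, `k_E` are
#'   used).
#' @param upper Upper end of the search interval.
#' @return Data frame with columns `root` and `stable`.
#' @export
e_kinetic_roots <- function(params, upper = 10) {
  stopifnot(inherits(params, "model_params"))
  f <- function(x) params$mu_E * hill(x, params$hill$e_self) - params$k_E * x
  xs <- seq(0, upper, length.out = 20001L)
  fx <- f(xs)
  roots <- numeric(0)
  if (abs(fx[1]) < 1e-12) roots <- c(roots, xs[1])
  sgn <- sign(fx)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-13)$root
    roots <- c(roots, r)
  }
  # exact zeros sitting on grid points (other than x = 0)
  on_grid <- xs[-1][abs(fx[-1]) < 1e-12]
  roots <- sort(unique(c(roots, on_grid)))
  eps <- 1e-6
  stable <- vapply(roots, function(r) {
    (f(r + eps) - f(max(r - eps, 0))) / (eps + min(eps, r)) < 0
  }, logical(1))
  data.frame(root = roots, stable = stable)
}

#' Upper stable signalling state of the E kinetics
#'
#' The largest stable root of the E-only reaction term; used as the default
#' amplitude for "elevated levels of E" initial conditions and as the
#' invaded-state reference for front tracking.
#'
#' @inheritParams e_kinetic_roots
#' @return A single numeric value.
#' @export
e_upper_root <- function(params, upper = 10) {
  r <- e_kinetic_roots(params, upper)
  r <- r$root[r$stable]
  if (!length(r)) stop("e_upper_root: no stable root found")
  max(r)
}
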