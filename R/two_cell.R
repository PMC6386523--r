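#' Two-cell Delta-Notch subsystem parameters
#'
#' The two-cell system isolates the Delta-Notch interactions that decide
#' whether lateral inhibition occurs (EGFR signalling and the cell state are
#' frozen): each cell's Notch is produced at basal rate `beta` plus
#' trans-activation `lambda * h(D_j)` by the neighbour's Delta, gated by
#' cis-inhibition `1 - h(D_i)` from its own Delta; Delta is produced at rate
#' `mu_D` under Notch repression `1 - h(N_i)`:
#' \deqn{dN_i/dt = [\beta + \lambda h(D_j)](1 - h(D_i)) - k_N N_i}
#' \deqn{dD_i/dt = \mu_D (1 - h(N_i)) - k_D D_i}
#' The system is symmetric under cell exchange.
#'
#' Defaults mirror the integrated-model parameter set (`lambda = mu_N`,
#' the `d_trans`, `d_cis`, `n_on_d` Hill specs).
#'
#' @param beta Basal Notch production rate.
#' @param lambda Delta-mediated (trans) Notch gain rate.
#' @param mu_D Delta production rate.
#' @param k_N,k_D Decay rates.
#' @param hill_trans,hill_cis,hill_nd [hill_spec()]s for trans-activation,
#'   cis-inhibition and Notch repression of Delta.
#' @param params Optional `model_params` to inherit defaults from.
#' @return An object of class `two_cell_params`.
#' @export
two_cell_params <- function(beta, lambda = NULL, mu_D = NULL,
                            k_N = NULL, k_D = NULL,
                            hill_trans = NULL, hill_cis = NULL,
                            hill_nd = NULL, params = model_params()) {
  p <- list(
    beta = beta,
    lambda = lambda %||% params$mu_N,
    mu_D = mu_D %||% params$mu_D,
    k_N = k_N %||% params$k_N,
    k_D = k_D %||% params$k_D,
    hill_trans = hill_trans %||% params$hill$d_trans,
    hill_cis = hill_cis %||% params$hill$d_cis,
    hill_nd = hill_nd %||% params$hill$n_on_d
  )
  if (p$beta < 0 || p$lambda < 0 || p$mu_D < 0 || p$k_N <= 0 || p$k_D <= 0)
    stop("two_cell_params: rates must be non-negative (decays positive)")
  structure(p, class = "two_cell_params")
}

#' Rates of the two-cell Delta-Notch system
#'
#' @param state Numeric length-4 vector `(D1, N1, D2, N2)`, non-negative.
#' @param params A [two_cell_params()].
#' @return Numeric length-4 vector of time derivatives, same ordering.
#' @export
two_cell_rates <- function(state, params) {
  stopifnot(inherits(params, "two_cell_params"), length(state) == 4L)
  if (any(state < 0)) stop("two_cell_rates: negative state")
  D <- state[c(1, 3)]; N <- state[c(2, 4)]
  dN <- (params$beta + params$lambda * hill(rev(D), params$hill_trans)) *
    (1 - hill(D, params$hill_cis)) - params$k_N * N
  dD <- params$mu_D * (1 - hill(N, params$hill_nd)) - params$k_D * D
  c(dD[1], dN[1], dD[2], dN[2])
}

#' Symmetric fixed point of the two-cell system
#'
#' Solves for the homogeneous state `(D*, N*, D*, N*)` reachable from rest:
#' substituting the N-nullcline into the D-equation gives a scalar root
#' problem in D, scanned for sign changes on `[0, mu_D/k_D]` and polished
#' with [stats::uniroot()]; the smallest root (the one connected to the
#' low-Delta rest state) is returned.
#'
#' @param params A [two_cell_params()].
#' @return Numeric `c(D = D*, N = N*)`.
#' @export
two_cell_fixed_point <- function(params) {
  stopifnot(inherits(params, "two_cell_params"))
  Nst <- function(D)
    (params$beta + params$lambda * hill(D, params$hill_trans)) *
      (1 - hill(D, params$hill_cis)) / params$k_N
  g <- function(D)
    params$mu_D * (1 - hill(Nst(D), params$hill_nd)) - params$k_D * D
  upper <- params$mu_D / params$k_D + 1
  xs <- seq(0, upper, length.out = 4001L)
  gx <- vapply(xs, g, numeric(1))
  if (abs(gx[1]) < 1e-12) {
    D <- 0
  } else {
    idx <- which(sign(gx[-1]) * sign(gx[-length(gx)]) < 0)
    if (!length(idx))
      stop("two_cell_fixed_point: no symmetric fixed point in bracket")
    i <- idx[1]
    D <- stats::uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-12)$root
  }
  c(D = D, N = Nst(D))
}

# numeric Jacobian of two_cell_rates at a state (central differences)
two_cell_jacobian <- function(state, params, eps = 1e-6) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    up <- state; up[j] <- up[j] + eps
    dn <- state; dn[j] <- max(dn[j] - eps, 0)
    J[, j] <- (two_cell_rates(up, params) - two_cell_rates(dn, params)) /
      (up[j] - dn[j])
  }
  J
}

#' Does lateral inhibition occur in the two-cell system?
#'
#' Locates the symmetric fixed point, evaluates the Jacobian there, and
#' projects it onto the exchange-symmetric and anti-symmetric subspaces
#' (perturbations with `dD1 = dD2` resp. `dD1 = -dD2`). Lateral inhibition
#' is declared when the symmetric state is stable against homogeneous
#' perturbations but unstable against anti-symmetric ones -- the signature
#' of Delta-Notch patterning, in which neighbouring cells amplify their
#' differences and acquire complementary fates. With `lambda = 0` the cells
#' are uncoupled, both subspace Jacobians coincide, and the criterion is
#' never met.
#'
#' @param params A [two_cell_params()].
#' @return Logical, with attributes `fixed_point`, `eig_antisym`,
#'   `eig_sym` (leading real parts).
#' @export
lateral_inhibition_occurs <- function(params) {
  fp <- two_cell_fixed_point(params)
  state <- c(fp[["D"]], fp[["N"]], fp[["D"]], fp[["N"]])
  J <- two_cell_jacobian(state, params)
  basis_a <- cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)) / sqrt(2)
  basis_s <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1)) / sqrt(2)
  eig_a <- max(Re(eigen(t(basis_a) %*% J %*% basis_a,
                        only.values = TRUE)$values))
  eig_s <- max(Re(eigen(t(basis_s) %*% J %*% basis_s,
                        only.values = TRUE)$values))
  structure(eig_a > 0 && eig_s < 0,
            fixed_point = fp, eig_antisym = eig_a, eig_sym = eig_s)
}

#' Integrate the two-cell system
#'
#' Fixed-step fourth-order Runge-Kutta integration (states clipped at zero),
#' used as the direct simulation route for classifying patterning.
#'
#' @param params A [two_cell_params()].
#' @param state0 Initial `(D1, N1, D2, N2)`.
#' @param t_end Final time.
#' @param dt Time step.
#' @return Final state (numeric length 4).
#' @export
simulate_two_cell <- function(params, state0, t_end = 200, dt = 0.01) {
  stopifnot(length(state0) == 4L)
  y <- pmax(as.numeric(state0), 0)
  n <- ceiling(t_end / dt)
  f <- function(s) two_cell_rates(pmax(s, 0), params)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- pmax(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  y
}

#' Simulation-based patterning classification
#'
#' Brute-force route independent of the linear-stability analysis: the
#' system is integrated from the symmetric fixed point perturbed
#' anti-symmetrically by 1%, and patterning is declared when the final
#' Delta difference `|D1 - D2|` exceeds 10% of the mean Delta level.
#'
#' @param params A [two_cell_params()].
#' @param t_end,dt Integration settings.
#' @return Logical.
#' @export
two_cell_pattern_sim <- function(params, t_end = 200, dt = 0.01) {
  fp <- two_cell_fixed_point(params)
  d0 <- max(fp[["D"]], 1e-3)
  s0 <- c(fp[["D"]] + 0.01 * d0, fp[["N"]],
          max(fp[["D"]] - 0.01 * d0, 0), fp[["N"]])
  s <- simulate_two_cell(params, s0, t_end = t_end, dt = dt)
  dbar <- mean(s[c(1, 3)])
  if (dbar <= 1e-9) return(FALSE)
  abs(s[1] - s[3]) > 0.1 * dbar
}

#' Two-cell lateral-inhibition phase diagram
#'
#' Classifies every point of a `(beta, lambda)` grid with
#' [lateral_inhibition_occurs()]. Per-point failures (e.g. no fixed point in
#' bracket) are recorded, not fatal.
#'
#' @param beta_grid,lambda_grid Increasing non-negative numeric grids.
#' @param params_base A [two_cell_params()] providing all non-axis
#'   parameters.
#' @param method `"stability"` (default) or `"simulation"` (oracle route).
#' @return Object of class `phase_diagram`: list with `beta`, `lambda`,
#'   `patterned` (logical matrix, rows = beta), `errors`.
#' @export
phase_diagram <- function(beta_grid, lambda_grid,
                          params_base = two_cell_params(beta = 1),
                          method = c("stability", "simulation")) {
  method <- match.arg(method)
  stopifnot(all(diff(beta_grid) > 0), all(diff(lambda_grid) > 0),
            all(beta_grid >= 0), all(lambda_grid >= 0))
  cls <- matrix(NA, length(beta_grid), length(lambda_grid),
                dimnames = list(beta = signif(beta_grid, 4),
                                lambda = signif(lambda_grid, 4)))
  errors <- list()
  for (i in seq_along(beta_grid)) for (j in seq_along(lambda_grid)) {
    p <- params_base
    p$beta <- beta_grid[i]
    p$lambda <- lambda_grid[j]
    res <- tryCatch(
      if (method == "stability") isTRUE(lateral_inhibition_occurs(p))
      else two_cell_pattern_sim(p),
      error = function(e) {
        errors[[length(errors) + 1L]] <<-
          list(beta = beta_grid[i], lambda = lambda_grid[j],
               message = conditionMessage(e))
        NA
      })
    cls[i, j] <- res
  }
  structure(list(beta = beta_grid, lambda = lambda_grid, patterned = cls,
                 errors = errors, method = method),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d x %d grid (%s), %d patterned, %d failed\n",
              length(x$beta), length(x$lambda), x$method,
              sum(x$patterned, na.rm = TRUE), sum(is.na(x$patterned))))
  invisible(x)
}
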