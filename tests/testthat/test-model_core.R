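test_that("Hill function matches its closed form and is a proper sigmoid", {
  hs <- hill_spec(3, 1)
  expect_equal(hill(0, hs), 0)
  expect_equal(hill(1, hs), 0.5)
  expect_equal(hill(2, hs), 8 / 9)
  # generalized threshold: half-activation exactly at a
  hs2 <- hill_spec(exponent = 4, threshold = 2.5)
  expect_equal(hill(2.5, hs2), 0.5)
  x <- seq(0, 50, by = 0.25)
  y <- hill(x, hs2)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0 & y < 1))
  expect_error(hill(-0.1, hs), "negative")
  expect_error(hill_spec(0, 1), "exponent")
  expect_error(hill_spec(3, -2), "threshold")
})

test_that("E-only reaction term reproduces the bistable kinetics", {
  p <- model_params("e_only", mu_E = 4, k_E = 1)
  expect_equal(reaction_E(cell_fields(phi_E = 0), p), 0)
  # mu*h(1) - k*1 = 4*0.5 - 1
  expect_equal(reaction_E(cell_fields(phi_E = 1), p), 1.0)
  expect_error(reaction_E(cell_fields(), model_params("e_l")), "variant")

  roots <- e_kinetic_roots(p)
  oracle <- e_roots_oracle(4, 1)
  expect_equal(nrow(roots), 3L)
  expect_equal(roots$root, oracle, tolerance = 1e-9)
  expect_equal(roots$stable, c(TRUE, FALSE, TRUE))
  expect_equal(e_upper_root(p), max(oracle), tolerance = 1e-9)
})

test_that("E+L reaction terms implement the excitable feedback", {
  p <- model_params("e_l", mu_E = 4, k_E = 1, mu_L = 0.4, k_L = 0.2,
                    hill = list(l_on_e = hill_spec(3, 1),
                                e_on_l = hill_spec(3, 1)))
  r0 <- reaction_EL(cell_fields(), p)
  expect_equal(unlist(r0), c(phi_E = 0, phi_L = 0))
  # mu_E h(1)(1 - h(0)) - k_E = 4 * 0.5 * 1 - 1
  r1 <- reaction_EL(cell_fields(phi_E = 1, phi_L = 0), p)
  expect_equal(r1$phi_E, 1.0)
  expect_equal(r1$phi_L, 0.2)
  # L'sc shutdown: at saturating L the E gain vanishes
  rbig <- reaction_EL(cell_fields(phi_E = 1, phi_L = 1e6), p)
  expect_equal(rbig$phi_E, -1 * 1, tolerance = 1e-9)
  expect_error(reaction_EL(cell_fields(), model_params("e_only")), "variant")
})

test_that("space-free E+L system is excitable: stable rest state, pulse returns", {
  p <- model_params("e_l", mu_E = 4, k_E = 1, mu_L = 0.4, k_L = 0.2,
                    hill = list(l_on_e = hill_spec(3, 1),
                                e_on_l = hill_spec(3, 1)))
  # the origin is locally stable: linearisation is diag(-k_E, -k_L)
  # (h'(0) = 0 for Hill exponent > 1)
  eps <- 1e-4
  r_eps <- reaction_EL(cell_fields(phi_E = eps, phi_L = eps), p)
  expect_lt(r_eps$phi_E, 0)
  expect_lt(r_eps$phi_L, 0)
  # independent ODE oracle (lsoda): super-threshold kick produces a large
  # transient excursion that returns to the rest state
  deriv <- function(t, y, parms) {
    r <- reaction_EL(cell_fields(phi_E = max(y[1], 0),
                                 phi_L = max(y[2], 0)), p)
    list(c(r$phi_E, r$phi_L))
  }
  out <- deSolve::ode(c(E = 1.5, L = 0), seq(0, 80, by = 0.5), deriv, NULL)
  expect_gt(max(out[, "E"]), 3)      # large excursion
  final <- out[nrow(out), ]
  expect_lt(final[["E"]], 1e-3)      # returns to rest
  expect_lt(final[["L"]], 0.05)
  # sub-threshold perturbation decays without an excursion
  out2 <- deSolve::ode(c(E = 0.3, L = 0), seq(0, 40, by = 0.5), deriv, NULL)
  expect_lt(max(out2[, "E"]), 0.5)
})

test_that("integrated kinetics: origin, basal Notch, and sign structure", {
  p0 <- model_params("integrated", beta = 0)
  r0 <- reaction_integrated(cell_fields(), 0, p0)
  expect_equal(unname(unlist(r0)), rep(0, 5))
  pb <- model_params("integrated", beta = 7)
  rb <- reaction_integrated(cell_fields(), 0, pb)
  expect_equal(rb$phi_N, 7)
  expect_equal(rb$phi_E + rb$phi_L + rb$phi_D + rb$omega, 0)
  expect_error(reaction_integrated(cell_fields(), -1, pb), "negative")
  expect_error(reaction_integrated(cell_fields(), 0, model_params("e_only")),
               "variant")

  # each regulatory arrow has the documented sign at a generic positive state
  p <- model_params("integrated")
  base <- list(E = 1.5, L = 1, D = 2, N = 4, Om = 0.3, Db = 1.5)
  rate <- function(st) {
    reaction_integrated(cell_fields(st$E, st$L, st$D, st$N, st$Om), st$Db, p)
  }
  partial <- function(field, wrt, eps = 1e-6) {
    up <- base; up[[wrt]] <- up[[wrt]] + eps
    dn <- base; dn[[wrt]] <- dn[[wrt]] - eps
    (rate(up)[[field]] - rate(dn)[[field]]) / (2 * eps)
  }
  expect_gt(partial("phi_E", "N"), 0)   # Notch upregulates EGFR signalling
  expect_lt(partial("phi_E", "L"), 0)   # L'sc shuts down EGFR gain
  expect_gt(partial("phi_L", "E"), 0)   # EGFR activates L'sc
  expect_lt(partial("phi_L", "N"), 0)   # Notch downregulates L'sc
  expect_gt(partial("phi_D", "E"), 0)   # EGFR upregulates Delta
  expect_lt(partial("phi_D", "N"), 0)   # Notch downregulates Delta
  expect_gt(partial("phi_N", "Db"), 0)  # trans-activation by neighbour Delta
  expect_lt(partial("phi_N", "D"), 0)   # cis-inhibition by own Delta
  expect_lt(partial("phi_N", "L"), 0)   # L'sc downregulates Notch
  expect_gt(partial("omega", "L"), 0)   # L'sc promotes the transition
  expect_gt(partial("omega", "E"), 0)   # EGFR promotes the transition
})

test_that("kinetics cannot push a field negative and the transition is irreversible", {
  p <- model_params("integrated")
  set.seed(4)
  for (i in 1:25) {
    st <- cell_fields(phi_E = runif(1, 0, 6), phi_L = runif(1, 0, 4),
                      phi_D = runif(1, 0, 20), phi_N = runif(1, 0, 15),
                      omega = runif(1))
    db <- runif(1, 0, 10)
    for (f in c("phi_E", "phi_L", "phi_D", "phi_N")) {
      st0 <- st
      st0[[f]] <- 0
      expect_gte(reaction_integrated(st0, db, p)[[f]], 0)
    }
    expect_gte(reaction_integrated(st, db, p)$omega, 0)
    st_nb <- st; st_nb$omega <- 1
    expect_equal(reaction_integrated(st_nb, db, p)$omega, 0)
  }
})

test_that("homogeneous Delta-Notch steady state is a root of the rate function", {
  # damped fixed-point iteration oracle for the (D, N) pair at rest
  # (E = L = 0, neighbours share the same D), beta = 10
  p <- model_params("integrated", beta = 10)
  D <- 0; N <- 0
  for (i in 1:4000) {
    r <- reaction_integrated(cell_fields(phi_D = D, phi_N = N), D, p)
    D <- max(D + 0.02 * r$phi_D, 0)
    N <- max(N + 0.02 * r$phi_N, 0)
  }
  r <- reaction_integrated(cell_fields(phi_D = D, phi_N = N), D, p)
  expect_lt(abs(r$phi_D), 1e-6)
  expect_lt(abs(r$phi_N), 1e-6)
  expect_gt(N, 5)   # basal-Notch dominated rest state
  expect_lt(D, 1)   # Delta held down
})

test_that("with gains off every field decays exponentially", {
  p <- model_params("integrated", eta = 0, mu_E = 0, mu_L = 0, mu_D = 0,
                    mu_N = 0, beta = 0, sigma_N = 0, k_Omega = 0,
                    k_E = 1, k_L = 0.5, k_D = 2, k_N = 0.25)
  lat <- quick_chain(5)
  st <- structure(list(phi_E = rep(2, 5), phi_L = rep(3, 5),
                       phi_D = rep(1, 5), phi_N = rep(4, 5),
                       omega = rep(0, 5)), class = "tissue_state")
  tr <- integrate_model(p, lat, st, t_end = 2, dt = 5e-4, record_every = 2)
  s <- state_at(tr, 2)
  expect_equal(s$phi_E[1], 2 * exp(-1 * 2), tolerance = 2e-3)
  expect_equal(s$phi_L[1], 3 * exp(-0.5 * 2), tolerance = 2e-3)
  expect_equal(s$phi_D[1], 1 * exp(-2 * 2), tolerance = 5e-3)
  expect_equal(s$phi_N[1], 4 * exp(-0.25 * 2), tolerance = 2e-3)
})
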