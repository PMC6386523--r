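test_that("pure decay integrates to the closed form", {
  p <- model_params("e_only", eta = 0, mu_E = 0, k_E = 1)
  lat <- quick_chain(10)
  tr <- integrate_model(p, lat, initial_condition("uniform", amplitude = 1),
                        t_end = 1, dt = 1e-3, record_every = 0.5)
  expect_equal(state_at(tr, 1)$phi_E, rep(exp(-1), 10), tolerance = 1e-3)
})

test_that("initial conditions select the documented cells", {
  hx <- build_hex_rect(20, 20)
  st <- apply_initial_condition(initial_condition("left_columns", columns = 3,
                                                  amplitude = 2), hx)
  expect_equal(sum(st$phi_E > 0), 60L)
  expect_true(all(st$phi_E[hx$col < 3] == 2))
  expect_equal(max(st$phi_L, st$phi_D, st$phi_N, st$omega), 0)

  disc <- build_hex_disc(15)
  ic <- initial_condition("angular_sector", theta = c(pi / 3, 5 * pi / 3),
                          amplitude = 1)
  st2 <- apply_initial_condition(ic, disc)
  sel <- which(st2$phi_E > 0)
  expect_gt(length(sel), 10)
  expect_true(all(disc$degree[sel] < 6L))                 # outer boundary only
  expect_true(all(disc$angle[sel] >= pi / 3 - 1e-9 &
                    disc$angle[sel] <= 5 * pi / 3 + 1e-9))
  st3 <- apply_initial_condition(initial_condition("uniform", amplitude = 0),
                                 disc)
  expect_equal(max(unlist(st3)), 0)
  expect_error(apply_initial_condition(ic, build_chain(10)), "disc")

  # default amplitude resolves to the upper stable root
  p <- model_params("e_only")
  st4 <- apply_initial_condition(initial_condition("left_columns"),
                                 build_chain(10), p)
  expect_equal(max(st4$phi_E), e_upper_root(p), tolerance = 1e-6)
})

test_that("bistable front invades towards the upper stable root", {
  p <- model_params("e_only", eta = 1)
  lat <- build_chain(120)
  tr <- integrate_model(p, lat, initial_condition("left_columns", columns = 3),
                        t_end = 60, dt = 0.05, record_every = 5)
  s <- state_at(tr, 60)
  expect_equal(s$phi_E[40], e_upper_root(p), tolerance = 1e-3)
  ws <- wave_speed(tr)
  expect_gt(ws$speed, 0.5)
  expect_gt(ws$r2, 0.999)
})

test_that("identical inputs give bitwise-identical trajectories", {
  p <- model_params("integrated", gamma = 2)
  lat <- quick_chain(20)
  ic <- initial_condition("left_columns", columns = 2)
  t1 <- integrate_model(p, lat, ic, t_end = 2, dt = 0.02, record_every = 1,
                        seed = 7)
  t2 <- integrate_model(p, lat, ic, t_end = 2, dt = 0.02, record_every = 1,
                        seed = 7)
  expect_identical(t1$states, t2$states)
  # gamma = 0 path is deterministic and seed-independent
  p0 <- model_params("integrated", gamma = 0)
  d1 <- integrate_model(p0, lat, ic, t_end = 2, dt = 0.02, record_every = 1)
  d2 <- integrate_model(p0, lat, ic, t_end = 2, dt = 0.02, record_every = 1,
                        seed = 99)
  expect_identical(d1$states, d2$states)
})

test_that("halving dt converges at first order", {
  p <- model_params("e_l", eta = 0.5, mu_L = 0.4, k_L = 0.2,
                    hill = list(l_on_e = hill_spec(3, 1),
                                e_on_l = hill_spec(3, 1)))
  lat <- quick_chain(40)
  ic <- initial_condition("left_columns", columns = 3)
  final_E <- function(dt) {
    tr <- integrate_model(p, lat, ic, t_end = 6, dt = dt, record_every = 6)
    state_at(tr, 6)$phi_E
  }
  ref <- final_E(0.1 / 16)
  e1 <- max(abs(final_E(0.1) - ref))
  e2 <- max(abs(final_E(0.05) - ref))
  e4 <- max(abs(final_E(0.025) - ref))
  order12 <- log2(e1 / e2)
  order24 <- log2(e2 / e4)
  expect_gt(order12, 0.9)
  expect_gt(order24, 0.9)
})

test_that("solutions are translation-equivariant away from the boundaries", {
  p <- model_params("e_only", eta = 0.5)
  lat <- build_chain(80)
  shift <- 7L
  tr1 <- integrate_model(p, lat,
                         initial_condition("cell_set", cells = 20:23,
                                           amplitude = 4),
                         t_end = 8, dt = 0.02, record_every = 8)
  tr2 <- integrate_model(p, lat,
                         initial_condition("cell_set", cells = 20:23 + shift,
                                           amplitude = 4),
                         t_end = 8, dt = 0.02, record_every = 8)
  a <- state_at(tr1, 8)$phi_E[15:60]
  b <- state_at(tr2, 8)$phi_E[15:60 + shift]
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("noise increments have zero mean: ensemble tracks the deterministic decay", {
  # gains off, noise on the Delta equation; D starts at 5 and decays at k_D
  p <- model_params("integrated", eta = 0, mu_E = 0, mu_L = 0, mu_D = 0,
                    mu_N = 0, beta = 0, sigma_N = 0, k_Omega = 0, gamma = 2,
                    k_D = 1)
  lat <- quick_chain(10)
  st <- structure(list(phi_E = numeric(10), phi_L = numeric(10),
                       phi_D = rep(5, 10), phi_N = numeric(10),
                       omega = numeric(10)), class = "tissue_state")
  finals <- vapply(1:200, function(seed) {
    tr <- integrate_model(p, lat, st, t_end = 1, dt = 0.01, record_every = 1,
                          seed = seed)
    mean(state_at(tr, 1)$phi_D)
  }, numeric(1))
  mc_se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 5 * exp(-1)), 4 * mc_se + 0.02)
  # fluctuation is present (not degenerate)
  expect_gt(stats::sd(finals), 0.01)
})

test_that("step-size and seed validation guard the integrator", {
  p <- model_params("integrated", gamma = 1)
  lat <- quick_chain(10)
  ic <- initial_condition("uniform", amplitude = 0)
  expect_error(integrate_model(p, lat, ic, t_end = 1, dt = 1),
               "stability")
  expect_error(integrate_model(p, lat, ic, t_end = 1, dt = 0.01),
               "seed")
})

test_that("trajectories round-trip through the plain-text container", {
  p <- model_params("integrated")
  lat <- quick_chain(12)
  tr <- integrate_model(p, lat, initial_condition("left_columns", columns = 2),
                        t_end = 3, dt = 0.02, record_every = 1)
  dir <- withr::local_tempdir()
  write_trajectory(tr, dir)
  back <- read_trajectory(dir)
  expect_equal(back$times, tr$times)
  for (i in seq_along(tr$states))
    expect_equal(back$states[[i]], tr$states[[i]], tolerance = 1e-12)
  expect_equal(back$params$mu_D, tr$params$mu_D)
  tab <- snapshot_table(tr, 3)
  expect_equal(nrow(tab), 12L)
  expect_equal(tab$E, state_at(tr, 3)$phi_E)
})
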