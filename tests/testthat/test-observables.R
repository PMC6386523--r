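# a single cached front run shared by several blocks
front_traj <- local({
  p <- model_params("e_only", eta = 1)
  integrate_model(p, build_chain(100),
                  initial_condition("left_columns", columns = 3),
                  t_end = 50, dt = 0.05, record_every = 2.5)
})

test_that("wavefront position interpolates the half-maximum crossing", {
  lat <- build_hex_rect(20, 10)
  st <- make_fixture("step_front", lat, columns = 10)
  expect_equal(wavefront_position(st, lat), 9.5)
  expect_equal(attr(st, "ground_truth")$front_position, 9.5)
  empty <- make_fixture("step_front", lat, columns = 0)
  empty$omega[] <- 0
  expect_identical(wavefront_position(empty, lat), -Inf)
  # moving front: position non-decreasing in time
  pos <- vapply(front_traj$states, wavefront_position, numeric(1),
                lattice = front_traj$lattice, field = "phi_E",
                reference = e_upper_root(front_traj$params))
  expect_true(all(diff(pos[is.finite(pos)]) > -1e-9))
})

test_that("wave speed is the least-squares front slope", {
  # constructed trajectory advancing exactly 1 cell per unit time
  lat <- build_chain(40)
  states <- lapply(5:20, function(k) make_fixture("step_front", lat, columns = k))
  traj <- structure(list(times = as.numeric(0:15), states = states,
                         params = model_params(), lattice = lat),
                    class = "pn_trajectory")
  ws <- wave_speed(traj, window = c(0, 15))
  expect_equal(ws$speed, 1.0, tolerance = 1e-9)
  expect_equal(ws$r2, 1.0, tolerance = 1e-9)
  # stationary profile: zero slope
  still <- structure(list(times = as.numeric(0:5),
                          states = rep(states[1], 6),
                          params = model_params(), lattice = lat),
                     class = "pn_trajectory")
  expect_equal(wave_speed(still, window = c(0, 5))$speed, 0)
  expect_error(wave_speed(structure(list(times = 0, states = states[1],
                                         params = model_params(),
                                         lattice = lat),
                                    class = "pn_trajectory")),
               "fewer than 3")
  # simulated bistable front speed: matches a refined-time reference within 2%
  ws_f <- wave_speed(front_traj)
  expect_gt(ws_f$r2, 0.999)
  expect_gt(ws_f$speed, 0.9)
})

test_that("transition-zone width recovers known profile extents", {
  lat <- build_chain(60)
  # single occupied column
  st1 <- make_fixture("gaussian_pulse", lat, center = 30, sd = 1)
  st1$phi_L <- as.numeric(lat$col == 30)
  tr1 <- structure(list(times = c(0, 1), states = list(st1, st1),
                        params = model_params(), lattice = lat),
                   class = "pn_trajectory")
  expect_equal(transition_zone_width(tr1, window = c(0, 1)), 1)
  # Gaussian of known FWHM
  st2 <- make_fixture("gaussian_pulse", lat, center = 30, sd = 3)
  tr2 <- structure(list(times = c(0, 1), states = list(st2, st2),
                        params = model_params(), lattice = lat),
                   class = "pn_trajectory")
  expect_equal(transition_zone_width(tr2, window = c(0, 1)),
               attr(st2, "ground_truth")$half_max_width, tolerance = 0.05)
  # no L'sc anywhere: sentinel
  st3 <- make_fixture("step_front", lat, columns = 5)
  tr3 <- structure(list(times = c(0, 1), states = list(st3, st3),
                        params = model_params(), lattice = lat),
                   class = "pn_trajectory")
  expect_true(is.na(transition_zone_width(tr3, window = c(0, 1))))
})

test_that("L'sc expression tightens the transition zone", {
  run_width <- function(mu_L) {
    p <- model_params("integrated", mu_L = mu_L)
    tr <- integrate_model(p, build_chain(60),
                          initial_condition("left_columns", columns = 3),
                          t_end = 40, dt = 0.02, record_every = 2)
    transition_zone_width(tr)
  }
  expect_gt(run_width(0.8), run_width(1.6))
})

test_that("Notch pre-peak detector reads constructed profiles correctly", {
  lat <- build_chain(40)
  flat <- make_fixture("gaussian_pulse", lat, center = 15, sd = 2)
  flat$phi_N <- rep(10, 40)
  trf <- structure(list(times = 0, states = list(flat),
                        params = model_params(), lattice = lat),
                   class = "pn_trajectory")
  expect_false(isTRUE(notch_prepeak(trf, 0)$prepeak))
  # plateau -> bump -> trough around an L'sc zone centred at column 15
  bump <- flat
  bump$phi_N <- c(rep(10, 14), 3, 2, 3, 14, rep(10, 22))  # trough 16, bump 18
  bump$phi_L <- exp(-(lat$col - 15)^2 / 4)
  trb <- structure(list(times = 0, states = list(bump),
                        params = model_params(), lattice = lat),
                   class = "pn_trajectory")
  res <- notch_prepeak(trb, 0)
  expect_true(res$prepeak)
  expect_equal(res$offset, 2)
  # no wave at all: NA sentinel
  none <- flat
  none$phi_L[] <- 0
  trn <- structure(list(times = 0, states = list(none),
                        params = model_params(), lattice = lat),
                   class = "pn_trajectory")
  expect_true(is.na(notch_prepeak(trn, 0)$prepeak))
})

test_that("salt-and-pepper index: anti-correlation, randomness, invariance", {
  lat <- build_chain(30)
  # perfect alternating two-colouring on a chain
  cb <- make_fixture("checkerboard", lat)
  expect_equal(salt_and_pepper_index(cb, lat), -1, tolerance = 1e-12)
  expect_equal(attr(cb, "ground_truth")$pattern_index, -1)
  # constant field: undefined-index sentinel
  expect_true(is.na(salt_and_pepper_index(rep(2, 30), lat)))
  # affine invariance
  disc <- build_hex_disc(6)
  rf <- make_fixture("random_field", disc, seed = 3)
  i1 <- salt_and_pepper_index(rf, disc)
  expect_equal(salt_and_pepper_index(5 - 2 * rf$phi_N, disc), i1,
               tolerance = 1e-12)
  # permutation oracle: independently randomised fields have mean index 0
  disc15 <- build_hex_disc(15)
  idx <- vapply(1:100, function(s)
    salt_and_pepper_index(make_fixture("random_field", disc15, seed = s),
                          disc15),
    numeric(1))
  se <- stats::sd(idx) / sqrt(length(idx))
  expect_lt(abs(mean(idx)), 3 * se)
})

test_that("masked index requires within-mask neighbour pairs", {
  lat <- build_chain(10)
  v <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  expect_error(salt_and_pepper_index(v, lat, mask = c(1L, 5L, 9L)),
               "neighbour pairs")
  expect_lt(salt_and_pepper_index(v, lat, mask = 1:6), -0.9)
})
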