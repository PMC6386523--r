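# shared small fixtures; everything heavier is built inside the test files

quick_chain <- function(n = 40) build_chain(n)

# independent closed-form oracle for the roots of mu*h(x) - k*x with
# n = 3, a = 1: positive roots of x^3 - (mu/k) x^2 + 1 = 0 via polyroot()
e_roots_oracle <- function(mu = 4, k = 1) {
  z <- polyroot(c(1, 0, -mu / k, 1))
  r <- Re(z[abs(Im(z)) < 1e-9 & Re(z) > 0])
  sort(c(0, r))
}

# test-side elementary-effects oracle: straightforward recomputation from
# the definition, structured differently from the package implementation
oracle_effects <- function(points, outputs, k) {
  eff <- vector("list", k)
  for (r in seq_along(points)) {
    x <- points[[r]]; y <- outputs[[r]]
    for (s in seq_len(nrow(x) - 1)) {
      d <- x[s + 1, ] - x[s, ]
      j <- which.max(abs(d))
      eff[[j]] <- c(eff[[j]], (y[s + 1] - y[s]) / d[j])
    }
  }
  eff
}

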