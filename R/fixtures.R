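#' Synthetic reference fields for testing observables
#'
#' Deterministic (or seeded) tissue states with known ground truth, used to
#' validate the wavefront, zone-width and pattern-index estimators:
#'
#' * `"step_front"` — Omega = 1 (and `phi_E` at the elevated state) on the
#'   first `columns` columns; ground-truth front position
#'   `columns - 0.5`.
#' * `"gaussian_pulse"` — Gaussian `phi_L` profile along the wave axis;
#'   ground-truth half-maximum width `2 sqrt(2 log 2) sd`.
#' * `"checkerboard"` — alternating two-colouring of `phi_N` (and `phi_D`
#'   in anti-phase); on a chain the ground-truth pattern index is -1.
#' * `"random_field"` — iid uniform `phi_N` and `phi_D`; zero expected
#'   pattern index.
#'
#' @param kind Fixture kind.
#' @param lattice A `cell_lattice`.
#' @param columns Step position for `"step_front"`.
#' @param center,sd Gaussian centre and standard deviation (wave-axis
#'   units) for `"gaussian_pulse"`.
#' @param seed RNG seed for `"random_field"`.
#' @return A `tissue_state` with attribute `ground_truth` (named list).
#' @export
make_fixture <- function(kind = c("step_front", "gaussian_pulse",
                                  "checkerboard", "random_field"),
                         lattice, columns = 10L, center = NULL, sd = 2,
                         seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(lattice, "cell_lattice"))
  n <- lattice$n_cells
  st <- list(phi_E = numeric(n), phi_L = numeric(n), phi_D = numeric(n),
             phi_N = numeric(n), omega = numeric(n))
  gt <- list()
  if (kind == "step_front") {
    sel <- lattice$col < columns
    st$omega[sel] <- 1
    st$phi_E[sel] <- 4
    gt$front_position <- columns - 0.5
  } else if (kind == "gaussian_pulse") {
    if (is.null(center)) center <- stats::median(lattice$col)
    st$phi_L <- exp(-(lattice$col - center)^2 / (2 * sd^2))
    gt$half_max_width <- 2 * sqrt(2 * log(2)) * sd
    gt$center <- center
  } else if (kind == "checkerboard") {
    parity <- if (lattice$kind == "chain_1d") lattice$col %% 2L
    else (lattice$col + round(lattice$coords$y / (sqrt(3) / 2))) %% 2L
    st$phi_N <- ifelse(parity == 0L, 2, 0)
    st$phi_D <- ifelse(parity == 0L, 0, 2)
    if (lattice$kind == "chain_1d") gt$pattern_index <- -1
  } else {
    if (is.null(seed)) stop("make_fixture: random_field needs a seed")
    set.seed(as.integer(seed))
    st$phi_N <- stats::runif(n)
    st$phi_D <- stats::runif(n)
    gt$pattern_index <- 0
  }
  structure(st, class = "tissue_state", ground_truth = gt)
}
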