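#' Model parameter sets
#'
#' [model_params()] assembles all kinetic rates, Hill specifications, the
#' diffusion constant and the noise strength for one of the three model
#' variants:
#'
#' * `"e_only"` — single-component EGFR signalling front:
#'   \eqn{\partial_t \phi_E = \eta \nabla^2 \phi_E + \mu_E h(\phi_E) - k_E \phi_E}.
#' * `"e_l"` — EGFR signalling plus the proneural gene L'sc, whose expression
#'   shuts EGFR signalling down as a consequence of the fate transition,
#'   turning the bistable front into an excitable pulse.
#' * `"integrated"` — EGFR (E), L'sc (L), Delta (D), Notch (N) and the
#'   cell-state variable Omega (0 = neuroepithelial, 1 = neuroblast) on a
#'   lattice, with juxtacrine Delta-Notch coupling (trans-activation,
#'   cis-inhibition, Notch repression of Delta) and basal Notch production
#'   `beta`.
#'
#' Rates are expressed in the natural units of the E subsystem: time in units
#' of the EGFR decay time (`k_E = 1`) and position in units of the cell
#' spacing. The integrated-model defaults are a reconstructed reference set,
#' chosen so that the documented qualitative behaviours hold (travelling
#' transition zone with colocalised E/L/D pulses and a Notch trough preceded
#' by a Notch peak; clone phenotypes; suppression of lateral inhibition at
#' high basal Notch); they can be overridden individually or from a config
#' file.
#'
#' Each regulatory link carries its own [hill_spec()], named by
#' regulator/target:
#' `e_self` (EGFR autocatalysis), `l_on_e` (L'sc shutdown of EGFR gain),
#' `n_on_e` (Notch upregulation of EGFR signalling, weight `sigma_N`),
#' `e_on_l`, `n_on_l` (EGFR activation / Notch repression of L'sc),
#' `e_on_d`, `n_on_d` (EGFR activation / Notch repression of Delta),
#' `d_trans` (trans-activation of Notch by neighbour Delta),
#' `d_cis` (cis-inhibition of Notch by own Delta),
#' `l_on_n` (L'sc downregulation of Notch),
#' `l_on_omega`, `e_on_omega`, `n_on_omega` (the two transition routes:
#' L'sc-driven, and EGFR-driven in the absence of Notch).
#'
#' @param variant One of `"e_only"`, `"e_l"`, `"integrated"`.
#' @param eta Diffusion constant of E (cell spacing squared per unit time).
#' @param mu_E,mu_L,mu_D,mu_N Gain rates of E, L, D, N.
#' @param k_E,k_L,k_D,k_N Decay rates of E, L, D, N.
#' @param beta Basal (ligand-independent) Notch gain rate.
#' @param sigma_N Weight of Notch upregulation of EGFR signalling.
#' @param k_Omega Cell-state transition rate.
#' @param gamma Biochemical noise strength (0 = deterministic).
#' @param notch_E How Notch upregulates EGFR signalling: `"additive"`
#'   (default; a Notch-driven basal E production term `sigma_N h(phi_N)`,
#'   which elevates the neuroepithelial EGFR rest state and thereby carries
#'   the front at small diffusion constants) or `"multiplicative"` (the
#'   boost `1 + sigma_N h(phi_N)` scales the autocatalytic E production and
#'   vanishes in cells without EGFR activity).
#' @param hill Named list of [hill_spec()]s; entries merge over the defaults.
#' @return An object of class `model_params`.
#' @export
model_params <- function(variant = c("integrated", "e_only", "e_l"),
                         eta = 0.15,
                         mu_E = 4, k_E = 1,
                         mu_L = 0.8, k_L = 0.25,
                         mu_D = 20, k_D = 0.7,
                         mu_N = 12, k_N = 1,
                         beta = 10,
                         sigma_N = 0.2,
                         k_Omega = 0.5,
                         gamma = 0,
                         notch_E = c("additive", "multiplicative"),
                         hill = list()) {
  variant <- match.arg(variant)
  notch_E <- match.arg(notch_E)
  rates <- c(eta = eta, mu_E = mu_E, k_E = k_E, mu_L = mu_L, k_L = k_L,
             mu_D = mu_D, k_D = k_D, mu_N = mu_N, k_N = k_N,
             beta = beta, sigma_N = sigma_N, k_Omega = k_Omega, gamma = gamma)
  if (!all(is.finite(rates))) stop("model_params: all rates must be finite")
  if (any(rates < 0))
    stop("model_params: negative rate(s): ",
         paste(names(rates)[rates < 0], collapse = ", "))
  hs <- default_hill_specs()
  if (length(hill)) {
    unknown <- setdiff(names(hill), names(hs))
    if (length(unknown))
      stop("model_params: unknown hill spec(s): ",
           paste(unknown, collapse = ", "))
    for (nm in names(hill)) {
      stopifnot(inherits(hill[[nm]], "hill_spec"))
      hs[[nm]] <- hill[[nm]]
    }
  }
  structure(c(as.list(rates),
              list(variant = variant, notch_E = notch_E, hill = hs)),
            class = "model_params")
}

default_hill_specs <- function() {
  list(
    e_self     = hill_spec(3, 1),
    l_on_e     = hill_spec(3, 2),
    n_on_e     = hill_spec(3, 5),
    e_on_l     = hill_spec(4, 1.5),
    n_on_l     = hill_spec(6, 11),
    e_on_d     = hill_spec(3, 1),
    n_on_d     = hill_spec(3, 3),
    d_trans    = hill_spec(3, 2),
    d_cis      = hill_spec(3, 5),
    l_on_n     = hill_spec(3, 0.7),
    l_on_omega = hill_spec(4, 1),
    e_on_omega = hill_spec(4, 3),
    n_on_omega = hill_spec(3, 5)
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> variant = %s\n", x$variant))
  nm <- c("eta", "mu_E", "k_E", "mu_L", "k_L", "mu_D", "k_D", "mu_N", "k_N",
          "beta", "sigma_N", "k_Omega", "gamma")
  cat("  ", paste(sprintf("%s = %g", nm, unlist(x[nm])), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Named parameter presets
#'
#' Returns the parameter set used for each reference scenario:
#' `"fig2a"` (single-component bistable front, mu = 4, n = 3),
#' `"fig2b"` (excitable E/L pulse, mu_L = 0.4, k_L = 0.2),
#' `"fig2e"` (integrated model on a 1D array, eta = 0.03),
#' `"fig3"` (integrated model, clone protocol on a 20 x 20 hexagonal patch),
#' `"fig4a"` / `"fig4b"` (integrated model with biochemical noise
#' gamma / mu_E = 0.5 on a disc; basal Notch gain beta = 10 suppresses
#' lateral inhibition, beta = 1 permits it).
#'
#' Presets are shipped as plain-text config files under
#' `system.file("extdata", "presets", package = "pnwave")`.
#'
#' @param name Preset name.
#' @return A `model_params` object.
#' @export
preset <- function(name = c("fig2a", "fig2b", "fig2e", "fig3",
                            "fig4a", "fig4b")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "pnwave", mustWork = TRUE)
  read_params_config(path)
}

params_to_list <- function(p) {
  out <- p[c("variant", "eta", "mu_E", "k_E", "mu_L", "k_L", "mu_D", "k_D",
             "mu_N", "k_N", "beta", "sigma_N", "k_Omega", "gamma", "notch_E")]
  out$hill <- lapply(p$hill, function(h)
    list(exponent = h$exponent, threshold = h$threshold))
  out
}

params_from_list <- function(x) {
  known <- c("variant", "eta", "mu_E", "k_E", "mu_L", "k_L", "mu_D", "k_D",
             "mu_N", "k_N", "beta", "sigma_N", "k_Omega", "gamma", "notch_E",
             "hill")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("params config: unknown key(s): ", paste(unknown, collapse = ", "))
  hill <- list()
  if (!is.null(x$hill)) {
    hill <- lapply(x$hill, function(h) {
      bad <- setdiff(names(h), c("exponent", "threshold"))
      if (length(bad))
        stop("params config: unknown hill key(s): ",
             paste(bad, collapse = ", "))
      hill_spec(exponent = h$exponent %||% 3, threshold = h$threshold %||% 1)
    })
  }
  args <- x[setdiff(names(x), "hill")]
  args$hill <- hill
  do.call(model_params, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write parameter configs
#'
#' Parameter sets serialise to a flat, human-editable YAML file with one key
#' per rate and a nested `hill:` section (one `exponent`/`threshold` pair per
#' regulatory link). Unknown keys are rejected on read.
#'
#' @param path File path.
#' @param params A `model_params` object.
#' @return `read_params_config` returns a `model_params`;
#'   `write_params_config` returns `path` invisibly.
#' @export
read_params_config <- function(path) {
  params_from_list(yaml::read_yaml(path))
}

#' @rdname read_params_config
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  yaml::write_yaml(params_to_list(params), path)
  invisible(path)
}
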