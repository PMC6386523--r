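#' Hill response specification
#'
#' A Hill function parameterises each nonlinear regulatory link of the model:
#' activation (or, as `1 - hill(...)`, inhibition) of a target by a regulator.
#' The response is \eqn{h(x) = (x/a)^n / (1 + (x/a)^n)}, a sigmoid rising from
#' 0 to 1 with half-activation at the threshold \eqn{a} and steepness set by
#' the Hill coefficient \eqn{n}. With \eqn{a = 1} this reduces to the plain
#' form \eqn{x^n / (1 + x^n)}.
#'
#' @param exponent Hill coefficient \eqn{n} (dimensionless, > 0).
#' @param threshold Half-activation level \eqn{a} (concentration units, > 0).
#' @return An object of class `hill_spec`.
#' @examples
#' hs <- hill_spec(exponent = 3, threshold = 1)
#' hill(1, hs)  # 0.5 at threshold
#' @export
hill_spec <- function(exponent = 3, threshold = 1) {
  stopifnot(is.numeric(exponent), length(exponent) == 1L, is.finite(exponent),
            is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  if (exponent <= 0) stop("hill_spec: `exponent` must be > 0")
  if (threshold <= 0) stop("hill_spec: `threshold` must be > 0")
  structure(list(exponent = as.numeric(exponent),
                 threshold = as.numeric(threshold)),
            class = "hill_spec")
}

#' @export
print.hill_spec <- function(x, ...) {
  cat(sprintf("<hill_spec> n = %g, a = %g\n", x$exponent, x$threshold))
  invisible(x)
}

#' Evaluate a Hill function
#'
#' Computes \eqn{h(x) = (x/a)^n / (1 + (x/a)^n)}, vectorised over `x`.
#' The value lies in \eqn{[0, 1)} for all finite non-negative inputs, is
#' strictly increasing, and equals exactly 1/2 at `x == threshold`.
#'
#' @param x Non-negative numeric vector of regulator levels.
#' @param spec A [hill_spec()] object.
#' @return Numeric vector of responses in `[0, 1)`.
#' @export
hill <- function(x, spec) {
  stopifnot(inherits(spec, "hill_spec"), is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) stop("hill: negative input")
  u <- (x / spec$threshold)^spec$exponent
  u / (1 + u)
}
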