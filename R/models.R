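#' The Venegas sigmoid pressure-volume equation
#'
#' Evaluates the four-parameter logistic
#' \eqn{V = a + b/(1 + e^{-(P - c)/d})}, originally proposed for the
#' sigmoid shape of respiratory pressure-volume curves. Volume is bounded
#' between the asymptotes `a` (low pressure) and `a + b` (high pressure)
#' and is strictly increasing in pressure.
#'
#' @param pressure Absolute pressure, cmH2O (numeric vector).
#' @param params A [venegas_params()] set (or named vector with a, b, c, d).
#' @return Volume in litres.
#' @seealso [venegas_pressure()] for the numeric inverse.
#' @examples
#' venegas_volume(25, venegas_params(a = 0, b = 10, c = 20, d = 5))
#' @export
venegas_volume <- function(pressure, params) {
  params <- as_venegas_params(params)
  stopifnot(is.numeric(pressure), all(is.finite(pressure)))
  params[["a"]] + params[["b"]] /
    (1 + exp(-(pressure - params[["c"]]) / params[["d"]]))
}

#' Invert the Venegas equation numerically
#'
#' Finds the pressure at which [venegas_volume()] equals `volume`, by
#' bracketed root search. The bracket starts at `c +/- 50 d` and is widened
#' geometrically if needed. Volumes must lie strictly inside the open
#' interval `(a, a + b)`; the asymptotes are unreachable.
#'
#' @param volume Volume in litres (vectorised).
#' @inheritParams venegas_volume
#' @param tol Convergence tolerance on volume, litres.
#' @return Pressure in cmH2O.
#' @export
venegas_pressure <- function(volume, params, tol = 1e-9) {
  params <- as_venegas_params(params)
  stopifnot(is.numeric(volume), all(is.finite(volume)))
  a <- params[["a"]]; b <- params[["b"]]
  c <- params[["c"]]; d <- params[["d"]]
  if (any(volume <= a | volume >= a + b)) {
    stop("volume outside the open interval (a, a + b); ",
         "the Venegas asymptotes are unreachable")
  }
  # analytic inverse of the logistic; root search retained as a guard for
  # extreme arguments where the closed form loses precision
  invert_one <- function(V) {
    frac <- (V - a) / b
    P <- c - d * log(1 / frac - 1)
    if (is.finite(P) && abs(venegas_volume(P, params) - V) < tol) return(P)
    lo <- c - 50 * d; hi <- c + 50 * d
    while (venegas_volume(lo, params) > V) lo <- c - 2 * (c - lo)
    while (venegas_volume(hi, params) < V) hi <- c + 2 * (hi - c)
    stats::uniroot(function(x) venegas_volume(x, params) - V,
                   c(lo, hi), tol = tol / max(1, b / d))$root
  }
  vapply(volume, invert_one, numeric(1))
}

#' The exponential elastic-recoil pressure-volume equation
#'
#' Evaluates \eqn{V = v + k \ln(P - p)}, a single-ended curve used to
#' describe elastic recoil where pressure rises in a near-asymptotic
#' fashion at high volumes only (unlike the doubly-asymptotic Venegas
#' sigmoid). Defined for pressures strictly above the asymptote `p`.
#'
#' @param pressure Absolute pressure, cmH2O; must exceed `params["p"]`.
#' @param params An [exp_params()] set (or named vector with v, k, p).
#' @return Volume in litres.
#' @seealso [exp_pressure()] for the closed-form inverse,
#'   [exp_compliance()] for the analytic derivative.
#' @examples
#' pars <- exp_params(v = 2.8, k = 2.0, p = 4.8)
#' exp_volume(16.3, pars)
#' @export
exp_volume <- function(pressure, params) {
  params <- as_exp_params(params)
  stopifnot(is.numeric(pressure), all(is.finite(pressure)))
  if (any(pressure <= params[["p"]])) {
    stop("pressure must exceed the asymptote p = ",
         format(params[["p"]]), " cmH2O")
  }
  params[["v"]] + params[["k"]] * log(pressure - params[["p"]])
}

#' Invert the exponential equation: pressure from volume
#'
#' The closed-form inverse \eqn{P = p + e^{(V - v)/k}} of [exp_volume()].
#' Strictly increasing and convex in volume: equal volume increments cost
#' ever larger pressure increments, the behaviour seen when inflating a
#' nearly full abdominal compartment.
#'
#' @param volume Volume in litres.
#' @inheritParams exp_volume
#' @return Absolute pressure in cmH2O.
#' @export
exp_pressure <- function(volume, params) {
  params <- as_exp_params(params)
  stopifnot(is.numeric(volume), all(is.finite(volume)))
  out <- params[["p"]] + exp((volume - params[["v"]]) / params[["k"]])
  if (any(!is.finite(out))) {
    stop("volume out of range: exp((V - v)/k) overflowed")
  }
  out
}

#' Analytic abdominal compliance under the exponential model
#'
#' Compliance is the ease of expansion, dV/dP. For the exponential model
#' this is \eqn{k/(P - p)} litres per cmH2O: compliance falls as pressure
#' rises, so a fixed added volume raises pressure more at high pressure
#' than at low pressure.
#'
#' @inheritParams exp_volume
#' @return Compliance in L/cmH2O.
#' @examples
#' exp_compliance(10, exp_params(v = 0, k = 2, p = 6))  # 0.5 L/cmH2O
#' @export
exp_compliance <- function(pressure, params) {
  params <- as_exp_params(params)
  stopifnot(is.numeric(pressure), all(is.finite(pressure)))
  if (any(pressure <= params[["p"]])) {
    stop("pressure must exceed the asymptote p = ",
         format(params[["p"]]), " cmH2O")
  }
  params[["k"]] / (pressure - params[["p"]])
}
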