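#' Parameter sets for the two candidate pressure-volume equations
#'
#' `exp_params()` builds a validated parameter set for the exponential
#' elastic-recoil equation \eqn{V = v + k \ln(P - p)}: `v` is a volume
#' offset (L), `k` a log-slope setting the curvature (L, must be positive),
#' and `p` a pressure asymptote (cmH2O) that the curve approaches as volume
#' decreases; `p` must lie below every pressure at which the model is
#' evaluated.
#'
#' `venegas_params()` builds a parameter set for the Venegas sigmoid
#' \eqn{V = a + b/(1 + e^{-(P - c)/d})}: `a` is the lower volume asymptote
#' (L), `b` the volume span (L, positive), `c` the inflection pressure
#' (cmH2O) and `d` the width of the transition (cmH2O, positive).
#'
#' @param v,k,p Exponential-model parameters (see Details).
#' @param a,b,c,d Venegas-model parameters (see Details).
#' @return A named numeric vector of class `"exp_params"` or
#'   `"venegas_params"`.
#' @examples
#' exp_params(v = 2.8, k = 2.0, p = 4.8)
#' venegas_params(a = 0, b = 12, c = 20, d = 5)
#' @export
exp_params <- function(v, k, p) {
  stopifnot(is.numeric(v), is.numeric(k), is.numeric(p),
            length(v) == 1L, length(k) == 1L, length(p) == 1L,
            is.finite(v), is.finite(k), is.finite(p))
  if (k <= 0) stop("exponential parameter k must be positive")
  structure(c(v = v, k = k, p = p), class = "exp_params")
}

#' @rdname exp_params
#' @export
venegas_params <- function(a, b, c, d) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            all(is.finite(c(a, b, c, d))))
  if (b <= 0) stop("Venegas parameter b (volume span) must be positive")
  if (d <= 0) stop("Venegas parameter d (width) must be positive")
  structure(c(a = a, b = b, c = c, d = d), class = "venegas_params")
}

# Coerce a named vector/list to a validated parameter set.
as_exp_params <- function(x) {
  if (inherits(x, "exp_params")) return(x)
  x <- unlist(x)
  if (!all(c("v", "k", "p") %in% names(x))) {
    stop("exponential parameters require named components v, k, p")
  }
  exp_params(x[["v"]], x[["k"]], x[["p"]])
}

as_venegas_params <- function(x) {
  if (inherits(x, "venegas_params")) return(x)
  x <- unlist(x)
  if (!all(c("a", "b", "c", "d") %in% names(x))) {
    stop("Venegas parameters require named components a, b, c, d")
  }
  venegas_params(x[["a"]], x[["b"]], x[["c"]], x[["d"]])
}

#' @export
print.exp_params <- function(x, digits = 4, ...) {
  cat("Exponential PV parameters: V = v + k * ln(P - p)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
print.venegas_params <- function(x, digits = 4, ...) {
  cat("Venegas PV parameters: V = a + b / (1 + exp(-(P - c)/d))\n")
  print(round(unclass(x), digits))
  invisible(x)
}
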