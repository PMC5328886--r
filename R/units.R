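#' Unit constants for pressure conversion and gas compression
#'
#' `CMH2O_PER_MMHG` is the conversion factor between millimetres of mercury
#' and centimetres of water (1 mmHg = 1.3595 cmH2O). `ATMOSPHERE_CMH2O` is
#' atmospheric pressure expressed in centimetres of water (1033 cmH2O),
#' the reference pressure used in the Boyle's-law volume correction.
#'
#' Internally the package works in cmH2O for all pressures, litres for
#' balloon volumes, and millilitres for tidal volumes and compliances;
#' conversions happen only at input/output boundaries.
#'
#' @format Length-one numeric constants.
#' @name unit-constants
NULL

#' @rdname unit-constants
#' @export
CMH2O_PER_MMHG <- 1.3595

#' @rdname unit-constants
#' @export
ATMOSPHERE_CMH2O <- 1033

#' Convert pressures between mmHg and cmH2O
#'
#' Clinical intra-abdominal pressure is usually reported in mmHg while
#' airway pressures are reported in cmH2O; a common scale (cmH2O) is needed
#' to compare them. The conversion uses 1 mmHg = 1.3595 cmH2O.
#'
#' @param x Numeric vector of pressures (finite).
#' @return Numeric vector of converted pressures.
#' @examples
#' mmhg_to_cmh2o(30)   # 40.785 cmH2O, the inflation stop pressure
#' cmh2o_to_mmhg(5.0)  # 3.678 mmHg, typical baseline IAP
#' @export
mmhg_to_cmh2o <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * CMH2O_PER_MMHG
}

#' @rdname mmhg_to_cmh2o
#' @export
cmh2o_to_mmhg <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x / CMH2O_PER_MMHG
}

#' Boyle's-law correction of an injected gas volume
#'
#' Air injected at ambient pressure is compressed once inside the abdomen.
#' The volume it actually occupies at an intra-abdominal pressure `iap`
#' (gauge, cmH2O) is `injected_volume * 1033 / (1033 + iap)`.
#'
#' @param injected_volume Gas volume injected at ambient pressure, litres
#'   (non-negative).
#' @param iap Intra-abdominal pressure in cmH2O (non-negative, gauge).
#' @return Corrected volume in litres; at most `injected_volume`, with
#'   equality only when `iap` is zero.
#' @examples
#' boyle_correct_step(1.0, 40.8)  # 0.962 L
#' @export
boyle_correct_step <- function(injected_volume, iap) {
  stopifnot(is.numeric(injected_volume), is.numeric(iap),
            all(is.finite(injected_volume)), all(is.finite(iap)))
  if (any(injected_volume < 0)) stop("injected_volume must be non-negative")
  if (any(iap < 0)) stop("iap must be non-negative")
  injected_volume * ATMOSPHERE_CMH2O / (ATMOSPHERE_CMH2O + iap)
}

#' Cumulative pressure-corrected additional intra-abdominal volume
#'
#' Given one animal's ordered inflation steps, converts each injected gas
#' volume to the volume it occupies at the intra-abdominal pressure measured
#' after that step (10-s equilibration in the experiment), and accumulates.
#' Element `i` of the result is the corrected additional intra-abdominal
#' volume present after step `i`.
#'
#' The post-step equilibrated pressure is used for each step's correction:
#' it is the pressure at which the newly injected gas has settled, and the
#' only measurement available at the step where the pressure changed.
#'
#' @param step_index Integer vector of step ordinals; 0 is the baseline step
#'   with no injected volume. Must be strictly increasing.
#' @param injected_volume Litres of gas injected at each step (0 at baseline).
#' @param iap Equilibrated intra-abdominal pressure (cmH2O) measured after
#'   each step.
#' @return Numeric vector of cumulative corrected volumes (litres), one per
#'   step, non-decreasing.
#' @examples
#' cumulative_corrected_iav(0:2, c(0, 1, 1), c(5, 10, 20))
#' @export
cumulative_corrected_iav <- function(step_index, injected_volume, iap) {
  stopifnot(length(step_index) == length(injected_volume),
            length(step_index) == length(iap))
  if (length(step_index) == 0L) return(numeric(0))
  if (any(diff(step_index) <= 0)) {
    stop("step_index must be strictly increasing (no duplicates)")
  }
  cumsum(boyle_correct_step(injected_volume, iap))
}
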