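#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 0.5 -> 1, -0.5 ->
#' -1), the convention used for reported pressures (1 decimal place) and
#' compliances (integers) in clinical tables; base [round()] rounds ties
#' to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Abdomino-thoracic transmission by pooled linear regression
#'
#' Regresses the rise in peak airway pressure on the rise in
#' intra-abdominal pressure, both taken relative to each animal's baseline
#' (zero-additional-volume) step and pooled across all animals and steps.
#' The slope is the fraction of an IAP change transmitted to the airway.
#'
#' @param delta_iap,delta_ppaw Pressure rises above baseline, cmH2O. At
#'   least 3 points; `delta_iap` must vary.
#' @return A list of class `"pv_transmission"`: `intercept` (cmH2O),
#'   `slope` (dimensionless), `r_squared`, `p_value` (slope t-test),
#'   `n_points`, and the fitted `lm` object.
#' @examples
#' x <- c(1, 5, 10, 20); transmission_regression(x, 0.14 + 0.43 * x)
#' @export
transmission_regression <- function(delta_iap, delta_ppaw) {
  stopifnot(is.numeric(delta_iap), is.numeric(delta_ppaw),
            length(delta_iap) == length(delta_ppaw),
            all(is.finite(delta_iap)), all(is.finite(delta_ppaw)))
  if (length(delta_iap) < 3L) stop("need at least 3 delta points")
  if (stats::sd(delta_iap) < .Machine$double.eps^0.5) {
    stop("degenerate predictor: delta_iap values are all identical")
  }
  fit <- stats::lm(delta_ppaw ~ delta_iap)
  slope <- unname(stats::coef(fit)[2L])
  n <- length(delta_iap)
  # R^2 and the slope test computed directly so degenerate inputs (constant
  # response, exact fits) give the well-defined limits rather than 0/0
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((delta_ppaw - mean(delta_ppaw))^2)
  r2 <- if (ss_tot < .Machine$double.eps) 0 else 1 - ss_res / ss_tot
  sxx <- sum((delta_iap - mean(delta_iap))^2)
  se <- sqrt(ss_res / (n - 2) / sxx)
  p_value <- if (se < .Machine$double.eps) {
    if (abs(slope) < .Machine$double.eps) 1 else 0
  } else {
    2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  structure(list(
    intercept = unname(stats::coef(fit)[1L]),
    slope = slope,
    r_squared = r2,
    p_value = p_value,
    n_points = n,
    lm = fit
  ), class = "pv_transmission")
}

#' @export
print.pv_transmission <- function(x, digits = 3, ...) {
  cat(sprintf("Abdomino-thoracic transmission (pooled OLS, n = %d)\n",
              x$n_points))
  cat(sprintf("  delta pPAW = %.2f + %.2f x delta IAP,  R^2 = %.2f, p = %s\n",
              x$intercept, x$slope, x$r_squared,
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}

#' Pooled baseline-relative pressure deltas from a cohort
#'
#' For each animal, subtracts the baseline-step (step 0) observed IAP and
#' pPAW from every later step's values; rows are pooled across animals.
#' The baseline step itself contributes no row (its delta is identically
#' zero by construction and carries no information about transmission).
#'
#' @param steps Cohort steps data frame (see [read_cohort()] schema) or a
#'   `pv_cohort` object.
#' @return Data frame with columns `animal_id`, `step_index`, `delta_iap`,
#'   `delta_ppaw` (cmH2O).
#' @export
cohort_deltas <- function(steps) {
  if (inherits(steps, "pv_cohort")) steps <- steps$steps
  stopifnot(is.data.frame(steps))
  out <- lapply(split(steps, steps$animal_id), function(d) {
    d <- d[order(d$step_index), ]
    if (d$step_index[1L] != 0L) {
      stop("animal ", d$animal_id[1L], " has no baseline (step 0) row")
    }
    if (nrow(d) < 2L) return(NULL)
    data.frame(animal_id = d$animal_id[-1L],
               step_index = d$step_index[-1L],
               delta_iap = d$iap_cmh2o[-1L] - d$iap_cmh2o[1L],
               delta_ppaw = d$ppaw_cmh2o[-1L] - d$ppaw_cmh2o[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Finite-difference compliance
#'
#' Compliance as the ratio of a volume change to the pressure change it
#' produces, in whatever pressure unit the inputs carry (mL/mmHg for the
#' grade table, mL/cmH2O for comparison with respiratory compliance).
#'
#' @param delta_volume Volume change, mL.
#' @param delta_pressure Pressure change (> 0).
#' @return Compliance, mL per unit pressure.
#' @examples
#' finite_difference_compliance(500, 7.9)  # 63.3 mL/mmHg
#' @export
finite_difference_compliance <- function(delta_volume, delta_pressure) {
  stopifnot(is.numeric(delta_volume), is.numeric(delta_pressure),
            all(is.finite(delta_volume)), all(is.finite(delta_pressure)))
  if (any(delta_pressure <= 0)) {
    stop("delta_pressure must be strictly positive")
  }
  delta_volume / delta_pressure
}

#' Dynamic respiratory system compliance
#'
#' Tidal volume divided by driving pressure (peak airway pressure minus
#' PEEP), emulating the value a ventilator reports breath by breath.
#'
#' @param tidal_volume Tidal volume, mL (> 0).
#' @param ppaw Peak airway pressure, cmH2O.
#' @param peep Positive end-expiratory pressure, cmH2O; must be below
#'   `ppaw`.
#' @return Compliance in mL/cmH2O.
#' @examples
#' crs_dynamic(331, 20.5, 5.0)
#' @export
crs_dynamic <- function(tidal_volume, ppaw, peep) {
  stopifnot(is.numeric(tidal_volume), is.numeric(ppaw), is.numeric(peep))
  if (any(tidal_volume <= 0)) stop("tidal_volume must be positive")
  if (any(ppaw <= peep)) stop("ppaw must exceed peep")
  tidal_volume / (ppaw - peep)
}

#' Predicted effect of a fixed added volume at each hypertension grade
#'
#' For each "given" IAP (baseline plus the lower bound of each
#' intra-abdominal hypertension grade), reads the additional
#' intra-abdominal volume off the fitted IAP curve, adds `delta_volume`,
#' and computes the resulting IAP, the IAP rise, the finite-difference
#' abdominal compliance over the increment, and the accompanying rise in
#' peak airway pressure. Airway pressure is read from the airway curve at
#' the abdominal volume implied by the IAP curve (shared volume axis).
#' The baseline row takes zero additional volume by convention and its
#' compliance is reported as `NA` (its pressure rise is nil at reporting
#' precision).
#'
#' @param iap_params,ppaw_params Exponential parameters of the IAP and
#'   peak-airway-pressure curves ([exp_params()]).
#' @param baseline_iap_mmhg Baseline IAP, mmHg.
#' @param grade_thresholds_mmhg Lower bounds of hypertension grades
#'   I, II, ... in mmHg, ascending.
#' @param delta_volume Added (incompressible) volume, litres; `0` yields a
#'   table of zero deltas with compliance absent.
#' @return A data frame of class `"pv_grade_table"`, one row per grade,
#'   with cmH2O and mmHg mirrors of each pressure column.
#' @examples
#' pars <- derive_default_iap_params()
#' grade_table(pars, fit_ppaw_curve_params(pars))
#' @export
grade_table <- function(iap_params, ppaw_params,
                        baseline_iap_mmhg = 3.7,
                        grade_thresholds_mmhg = c(12, 16, 21, 26),
                        delta_volume = 0.5) {
  iap_params <- as_exp_params(iap_params)
  ppaw_params <- as_exp_params(ppaw_params)
  stopifnot(delta_volume >= 0)
  if (is.unsorted(grade_thresholds_mmhg, strictly = TRUE)) {
    stop("grade_thresholds_mmhg must be strictly ascending")
  }
  if (baseline_iap_mmhg >= grade_thresholds_mmhg[1L]) {
    stop("baseline IAP must lie below the first grade threshold")
  }
  given_mmhg <- c(baseline_iap_mmhg, grade_thresholds_mmhg)
  given_cmh2o <- mmhg_to_cmh2o(given_mmhg)
  if (any(given_cmh2o <= iap_params[["p"]])) {
    stop("a given IAP lies at or below the model's pressure asymptote")
  }
  labels <- c("baseline",
              as.character(utils::as.roman(seq_along(grade_thresholds_mmhg))))

  v_given <- c(0, exp_volume(given_cmh2o[-1L], iap_params))
  v_after <- v_given + delta_volume
  ppaw_given <- exp_pressure(v_given, ppaw_params)
  if (delta_volume == 0) {
    # adding nothing changes nothing: deltas are identically zero
    iap_after <- given_cmh2o
    ppaw_after <- ppaw_given
  } else {
    iap_after <- exp_pressure(v_after, iap_params)
    ppaw_after <- exp_pressure(v_after, ppaw_params)
  }
  delta_iap <- iap_after - given_cmh2o
  delta_iap_mmhg <- cmh2o_to_mmhg(delta_iap)
  cab <- rep(NA_real_, length(given_mmhg))
  if (delta_volume > 0) {
    idx <- which(labels != "baseline" & delta_iap_mmhg > 0)
    cab[idx] <- finite_difference_compliance(delta_volume * 1000,
                                             delta_iap_mmhg[idx])
  }
  out <- data.frame(
    grade = labels,
    given_iap_cmh2o = given_cmh2o,
    given_iap_mmhg = given_mmhg,
    ppaw_cmh2o = ppaw_given,
    additional_iav_l = v_given,
    iav_plus_delta_l = v_after,
    iap_after_cmh2o = iap_after,
    iap_after_mmhg = cmh2o_to_mmhg(iap_after),
    delta_iap_cmh2o = delta_iap,
    delta_iap_mmhg = delta_iap_mmhg,
    cab_ml_per_mmhg = cab,
    delta_ppaw_cmh2o = ppaw_after - ppaw_given,
    stringsAsFactors = FALSE
  )
  attr(out, "delta_volume") <- delta_volume
  class(out) <- c("pv_grade_table", "data.frame")
  out
}

#' @export
print.pv_grade_table <- function(x, ...) {
  cat(sprintf(
    "Predicted effect of an additional %.0f mL intra-abdominal volume\n",
    attr(x, "delta_volume") * 1000))
  disp <- data.frame(
    grade = x$grade,
    `given IAP` = sprintf("%.1f (%.1f)",
                          round_half_away(x$given_iap_cmh2o, 1),
                          round_half_away(x$given_iap_mmhg, 1)),
    pPAW = sprintf("%.1f", round_half_away(x$ppaw_cmh2o, 1)),
    `IAV (L)` = sprintf("%.1f", round_half_away(x$additional_iav_l, 1)),
    `IAV+d (L)` = sprintf("%.1f", round_half_away(x$iav_plus_delta_l, 1)),
    `IAP after` = sprintf("%.1f (%.1f)",
                          round_half_away(x$iap_after_cmh2o, 1),
                          round_half_away(x$iap_after_mmhg, 1)),
    `dIAP` = sprintf("%.1f (%.1f)",
                     round_half_away(x$delta_iap_cmh2o, 1),
                     round_half_away(x$delta_iap_mmhg, 1)),
    `CAB mL/mmHg` = ifelse(is.na(x$cab_ml_per_mmhg), "-",
                           sprintf("%.0f",
                                   round_half_away(x$cab_ml_per_mmhg))),
    `dpPAW` = sprintf("%.1f", round_half_away(x$delta_ppaw_cmh2o, 1)),
    check.names = FALSE
  )
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Airway-curve parameters implied by the transmission line
#'
#' Composes the IAP curve with a linear abdomino-thoracic transmission
#' (delta pPAW = intercept + slope * delta IAP above baseline) to obtain
#' the peak-airway-pressure curve as a function of additional volume. The
#' composition stays within the exponential family:
#' \eqn{pPAW(V) = p' + e^{(V - v')/k}} with `p' = baseline_ppaw +
#' intercept + slope (p - baseline_iap)`, `v' = v - k ln(slope)`.
#' Useful for constructing a synthetic airway curve consistent with the
#' generator's defaults, e.g. to drive [grade_table()].
#'
#' @param iap_params IAP curve parameters ([exp_params()]).
#' @param baseline_ppaw,baseline_iap Baselines, cmH2O.
#' @param slope,intercept Transmission line.
#' @return An [exp_params()] set for the airway curve.
#' @export
fit_ppaw_curve_params <- function(iap_params, baseline_ppaw = 20.5,
                                  baseline_iap = 5.0, slope = 0.43,
                                  intercept = 0.14) {
  iap_params <- as_exp_params(iap_params)
  stopifnot(slope > 0)
  exp_params(
    v = iap_params[["v"]] - iap_params[["k"]] * log(slope),
    k = iap_params[["k"]],
    p = baseline_ppaw + intercept +
      slope * (iap_params[["p"]] - baseline_iap)
  )
}
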