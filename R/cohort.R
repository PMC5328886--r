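#' Solve exponential parameters from three anchor points
#'
#' Finds the unique exponential parameter set \eqn{V = v + k \ln(P - p)}
#' whose curve passes through three (volume, pressure) anchors. Eliminating
#' `v` and `k` between point pairs leaves one equation in the asymptote `p`,
#' solved by bracketed root search below the smallest anchor pressure; `v`
#' and `k` then follow in closed form.
#'
#' @param volume,pressure Numeric length-3 vectors of anchor volumes (L)
#'   and absolute pressures (cmH2O); pressures must be distinct and
#'   increase with volume.
#' @param tol Root-finding tolerance on `p`.
#' @return An [exp_params()] set reproducing each anchor to < 1e-6 cmH2O.
#' @export
exp_params_from_anchors <- function(volume, pressure, tol = 1e-12) {
  stopifnot(length(volume) == 3L, length(pressure) == 3L,
            all(is.finite(volume)), all(is.finite(pressure)))
  o <- order(volume)
  volume <- volume[o]; pressure <- pressure[o]
  if (any(diff(pressure) <= 0)) {
    stop("anchor pressures must increase with volume")
  }
  dv21 <- volume[2] - volume[1]
  dv31 <- volume[3] - volume[1]
  f <- function(p) {
    dv31 * log((pressure[2] - p) / (pressure[1] - p)) -
      dv21 * log((pressure[3] - p) / (pressure[1] - p))
  }
  # scan geometrically below min(P) for a sign change, then refine
  hi <- pressure[1] - 1e-9
  offs <- c(1e-6 * 2^(0:60))
  offs <- offs[offs < 1e6]
  grid <- pressure[1] - offs
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (length(flip) == 0L) {
    stop("no asymptote solution below the smallest anchor pressure; ",
         "the three anchors are inconsistent with an exponential curve")
  }
  root <- stats::uniroot(f, c(grid[flip[1] + 1L], grid[flip[1]]),
                         tol = tol)$root
  k <- dv21 / log((pressure[2] - root) / (pressure[1] - root))
  v <- volume[1] - k * log(pressure[1] - root)
  exp_params(v = v, k = k, p = root)
}

#' Default intra-abdominal pressure-volume parameters
#'
#' Derives the exponential parameter set used as the generator's mean IAP
#' curve from three anchor conditions of the porcine inflation experiment:
#' baseline IAP 5.0 cmH2O at no additional volume, 16.3 cmH2O (grade-I
#' hypertension) at 7.7 L, and 49.4 cmH2O at the mean maximal inflation of
#' 10.4 L.
#'
#' @return An [exp_params()] set satisfying all three anchors to < 1e-6
#'   cmH2O.
#' @examples
#' pars <- derive_default_iap_params()
#' exp_pressure(c(0, 7.7, 10.4), pars)  # 5.0, 16.3, 49.4
#' @export
derive_default_iap_params <- function() {
  exp_params_from_anchors(volume = c(0, 7.7, 10.4),
                          pressure = c(5.0, 16.3, 49.4))
}

#' Configuration for the synthetic inflation-experiment generator
#'
#' Collects the conditions of a virtual stepwise abdominal-inflation
#' experiment: cohort size, the mean IAP curve, between-animal spread,
#' baseline pressures, the abdomino-thoracic transmission line, pressure
#' measurement noise, step size and stopping rule, and ventilation
#' settings. Defaults emulate the porcine protocol the analysis targets:
#' 7 animals, 1-L air increments, inflation stopped once IAP exceeds
#' 40.8 cmH2O (30 mmHg), baseline IAP 5.0 cmH2O, baseline peak airway
#' pressure 20.5 cmH2O, transmission slope 0.43 with intercept 0.14 cmH2O,
#' tidal volume 331 mL at PEEP 5 cmH2O.
#'
#' @param n_animals Number of virtual animals.
#' @param iap_params_mean Mean IAP curve parameters ([exp_params()]);
#'   default [derive_default_iap_params()].
#' @param between_animal_sd Relative between-animal SD applied to each of
#'   (v, k, p): multiplicative log-normal on v and k, additive Gaussian of
#'   SD `between_animal_sd * |p|` on p (clamped below
#'   `baseline_iap - 0.5`).
#' @param baseline_iap,baseline_ppaw Baseline intra-abdominal and peak
#'   airway pressures, cmH2O.
#' @param transmission_slope,transmission_intercept The generating
#'   abdomino-thoracic transmission line: above baseline, delta pPAW =
#'   intercept + slope * delta IAP.
#' @param iap_noise_sd,ppaw_noise_sd SD of additive Gaussian measurement
#'   noise on the two pressures, cmH2O.
#' @param injected_step Gas volume injected per step at ambient pressure, L.
#' @param stop_iap Inflation stops after the first step whose observed IAP
#'   exceeds this pressure, cmH2O.
#' @param max_steps Hard cap on inflation steps.
#' @param peep Positive end-expiratory pressure, cmH2O.
#' @param tidal_volume Tidal volume, mL.
#' @param seed Parent seed; per-animal sub-streams are derived from it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_animals = 7L,
                          iap_params_mean = derive_default_iap_params(),
                          between_animal_sd = 0.10,
                          baseline_iap = 5.0,
                          baseline_ppaw = 20.5,
                          transmission_slope = 0.43,
                          transmission_intercept = 0.14,
                          iap_noise_sd = 0.5,
                          ppaw_noise_sd = 0.5,
                          injected_step = 1.0,
                          stop_iap = 40.8,
                          max_steps = 20L,
                          peep = 5.0,
                          tidal_volume = 331,
                          seed = 1L) {
  iap_params_mean <- as_exp_params(iap_params_mean)
  stopifnot(n_animals >= 1L, between_animal_sd >= 0,
            iap_noise_sd >= 0, ppaw_noise_sd >= 0,
            injected_step > 0, stop_iap > baseline_iap,
            max_steps >= 1L, baseline_ppaw > peep, tidal_volume > 0)
  structure(list(
    n_animals = as.integer(n_animals),
    iap_params_mean = iap_params_mean,
    between_animal_sd = between_animal_sd,
    baseline_iap = baseline_iap,
    baseline_ppaw = baseline_ppaw,
    transmission_slope = transmission_slope,
    transmission_intercept = transmission_intercept,
    iap_noise_sd = iap_noise_sd,
    ppaw_noise_sd = ppaw_noise_sd,
    injected_step = injected_step,
    stop_iap = stop_iap,
    max_steps = as.integer(max_steps),
    peep = peep,
    tidal_volume = tidal_volume,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic inflation-cohort configuration\n")
  cat(sprintf("  %d animals, %.1f-L steps, stop above %.1f cmH2O (max %d steps)\n",
              x$n_animals, x$injected_step, x$stop_iap, x$max_steps))
  cat(sprintf("  mean IAP curve: v=%.4f k=%.4f p=%.4f; between-animal SD %.2f\n",
              x$iap_params_mean[["v"]], x$iap_params_mean[["k"]],
              x$iap_params_mean[["p"]], x$between_animal_sd))
  cat(sprintf("  transmission: dpPAW = %.2f + %.2f dIAP; noise SD (iap, ppaw) = (%.2f, %.2f)\n",
              x$transmission_intercept, x$transmission_slope,
              x$iap_noise_sd, x$ppaw_noise_sd))
  cat(sprintf("  baseline IAP %.1f, pPAW %.1f, PEEP %.1f cmH2O, VT %g mL, seed %d\n",
              x$baseline_iap, x$baseline_ppaw, x$peep, x$tidal_volume,
              x$seed))
  invisible(x)
}

# Animal-level true parameters: multiplicative log-normal spread on (v, k),
# additive Gaussian on p, clamped so the asymptote stays below baseline.
draw_animal_params <- function(config, rng) {
  m <- config$iap_params_mean
  sd <- config$between_animal_sd
  if (sd == 0) return(m)
  v <- m[["v"]] * rng$lnorm(1, meanlog = 0, sdlog = sd)
  k <- m[["k"]] * rng$lnorm(1, meanlog = 0, sdlog = sd)
  p <- m[["p"]] + rng$norm(1, sd = sd * abs(m[["p"]]))
  p <- min(p, config$baseline_iap - 0.5)
  exp_params(v = v, k = k, p = p)
}

# Post-step IAP consistent with Boyle compression of the newly injected
# gas: IAP* = P(V_prev + inj * 1033/(1033 + IAP*)). Fixed-point iteration.
boyle_fixed_point <- function(v_prev, injected, params, iap_start,
                              tol = 1e-8, max_iter = 200L) {
  iap <- iap_start
  for (i in seq_len(max_iter)) {
    v_new <- v_prev + boyle_correct_step(injected, iap)
    iap_next <- exp_pressure(v_new, params)
    if (abs(iap_next - iap) < tol) {
      return(list(iap = iap_next, volume = v_new))
    }
    iap <- iap_next
  }
  list(iap = iap, volume = v_prev + boyle_correct_step(injected, iap))
}

#' Simulate one virtual animal's stepwise inflation series
#'
#' Draws animal-level true curve parameters, then iterates 1-L (by default)
#' air injections: each injection is compressed per Boyle's law at the
#' equilibrated post-step pressure (solved as a fixed point), the true IAP
#' follows the animal's exponential curve at the cumulative true volume,
#' and the true peak airway pressure follows the transmission line above
#' its baseline value. Observed pressures add independent Gaussian noise.
#' Inflation stops after the first step whose observed IAP exceeds
#' `config$stop_iap`, or at `config$max_steps` (flagged if the stop
#' pressure was never reached).
#'
#' @param config A [cohort_config()].
#' @param animal_id Identifier used in the output (e.g. `"pig1"`).
#' @param seed Seed for this animal's private random stream.
#' @return A list of class `"animal_series"`: `steps` (data frame in the
#'   cohort CSV schema), `true_params`, and `reached_stop` flag.
#' @export
simulate_animal <- function(config, animal_id, seed) {
  stopifnot(inherits(config, "cohort_config"))
  rng <- local_rng(seed)
  pars <- draw_animal_params(config, rng)

  baseline_iap_true <- exp_pressure(0, pars)
  iap_t <- baseline_iap_true
  ppaw_t <- config$baseline_ppaw
  iap_obs <- iap_t + rng$norm(1, sd = config$iap_noise_sd)
  ppaw_obs <- ppaw_t + rng$norm(1, sd = config$ppaw_noise_sd)
  injected_volume <- 0
  v_true <- 0
  iap_true <- baseline_iap_true

  # inflate until the first step whose *observed* IAP exceeds the stop
  # pressure, or until max_steps
  reached_stop <- FALSE
  while (length(injected_volume) - 1L < config$max_steps) {
    step <- boyle_fixed_point(v_true, config$injected_step, pars, iap_true)
    v_true <- step$volume
    iap_true <- step$iap
    ppaw_true <- config$baseline_ppaw + config$transmission_intercept +
      config$transmission_slope * (iap_true - baseline_iap_true)
    injected_volume <- c(injected_volume, config$injected_step)
    iap_t <- c(iap_t, iap_true)
    ppaw_t <- c(ppaw_t, ppaw_true)
    iap_obs <- c(iap_obs, iap_true + rng$norm(1, sd = config$iap_noise_sd))
    ppaw_obs <- c(ppaw_obs,
                  ppaw_true + rng$norm(1, sd = config$ppaw_noise_sd))
    if (iap_obs[length(iap_obs)] > config$stop_iap) {
      reached_stop <- TRUE
      break
    }
  }

  keep <- seq_along(iap_obs)
  ppaw_obs <- pmax(ppaw_obs, config$peep + 0.5)  # physical floor
  steps <- data.frame(
    animal_id = animal_id,
    step_index = keep - 1L,
    injected_volume_l = injected_volume,
    corrected_additional_iav_l =
      cumulative_corrected_iav(keep - 1L, injected_volume, pmax(iap_obs, 0)),
    iap_cmh2o = iap_obs,
    ppaw_cmh2o = ppaw_obs,
    peep_cmh2o = config$peep,
    tidal_volume_ml = config$tidal_volume,
    stringsAsFactors = FALSE
  )
  steps$crs_ml_per_cmh2o <- crs_dynamic(steps$tidal_volume_ml,
                                        steps$ppaw_cmh2o,
                                        steps$peep_cmh2o)
  if (!reached_stop) {
    warning("animal ", animal_id, " did not reach stop_iap within max_steps")
  }
  structure(list(steps = steps, true_params = pars,
                 true_iap = iap_t[keep], true_ppaw = ppaw_t[keep],
                 reached_stop = reached_stop),
            class = "animal_series")
}

#' Simulate a cohort of virtual inflation experiments
#'
#' Runs [simulate_animal()] for `config$n_animals` animals on independent
#' random sub-streams derived deterministically from `config$seed`, so the
#' whole cohort is reproducible bit-for-bit from the configuration.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"pv_cohort"`: `steps` (pooled data frame, the
#'   cohort CSV schema), `truth` (per-animal true parameters),
#'   `animals` (list of `animal_series`), and `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_animals = 2, seed = 42))
#' head(coh$steps)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_subseeds(config$seed, config$n_animals)
  ids <- paste0("pig", seq_len(config$n_animals))
  animals <- Map(function(id, s) simulate_animal(config, id, s), ids, seeds)
  steps <- do.call(rbind, lapply(animals, `[[`, "steps"))
  rownames(steps) <- NULL
  truth <- do.call(rbind, lapply(animals, function(a) {
    data.frame(animal_id = a$steps$animal_id[1L],
               v = a$true_params[["v"]],
               k = a$true_params[["k"]],
               p = a$true_params[["p"]],
               reached_stop = a$reached_stop,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  structure(list(steps = steps, truth = truth, animals = animals,
                 config = config),
            class = "pv_cohort")
}

#' @export
print.pv_cohort <- function(x, ...) {
  n_steps <- table(x$steps$animal_id)
  cat(sprintf("Synthetic inflation cohort: %d animals, %d steps total\n",
              x$config$n_animals, nrow(x$steps)))
  top <- stats::aggregate(iap_cmh2o ~ animal_id, data = x$steps, FUN = max)
  cat(sprintf("  final IAP range %.1f - %.1f cmH2O; steps per animal %d - %d\n",
              min(top$iap_cmh2o), max(top$iap_cmh2o),
              min(n_steps), max(n_steps)))
  invisible(x)
}
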