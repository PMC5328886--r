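cohort_required_cols <- c("animal_id", "step_index", "injected_volume_l",
                          "iap_cmh2o", "ppaw_cmh2o", "peep_cmh2o",
                          "tidal_volume_ml")
cohort_optional_cols <- c("corrected_additional_iav_l", "crs_ml_per_cmh2o")

#' Write an inflation cohort to CSV
#'
#' Writes the cohort step table (one row per animal per inflation step) in
#' the package's plain-text schema: `animal_id`, `step_index`,
#' `injected_volume_l`, `corrected_additional_iav_l`, `iap_cmh2o`,
#' `ppaw_cmh2o`, `peep_cmh2o`, `tidal_volume_ml`, `crs_ml_per_cmh2o`.
#'
#' @param cohort A `pv_cohort` object or a steps data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  steps <- if (inherits(cohort, "pv_cohort")) cohort$steps else cohort
  stopifnot(is.data.frame(steps),
            all(cohort_required_cols %in% names(steps)))
  utils::write.csv(steps, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an inflation cohort from CSV
#'
#' Reads and validates a cohort step table written by [write_cohort()] (or
#' prepared by hand in the same schema). Extra columns are kept with a
#' warning; missing required columns, non-numeric cells, duplicate
#' (animal, step) pairs, or a missing baseline row are errors that name
#' the offending column or row.
#'
#' @param path CSV path.
#' @return Steps data frame sorted by animal and step index. If the
#'   `corrected_additional_iav_l` column is absent it is recomputed from
#'   the injected volumes and pressures.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse cohort file: ",
                             conditionMessage(e)))
  if (nrow(raw) == 0L) stop("empty cohort file: ", path)
  missing_cols <- setdiff(cohort_required_cols, names(raw))
  if (length(missing_cols)) {
    stop("cohort file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), c(cohort_required_cols, cohort_optional_cols))
  if (length(extra)) {
    warning("ignoring unrecognised column(s): ",
            paste(extra, collapse = ", "))
  }
  num_cols <- setdiff(intersect(c(cohort_required_cols,
                                  cohort_optional_cols), names(raw)),
                      "animal_id")
  for (cl in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      stop("non-numeric or non-finite value in column '", cl,
           "' at data row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
    raw[[cl]] <- vals
  }
  key <- paste(raw$animal_id, raw$step_index)
  if (anyDuplicated(key)) {
    stop("duplicate (animal_id, step_index) at data row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  raw <- raw[order(raw$animal_id, raw$step_index), , drop = FALSE]
  rownames(raw) <- NULL
  for (d in split(raw, raw$animal_id)) {
    if (d$step_index[1L] != 0 || d$injected_volume_l[1L] != 0) {
      stop("animal ", d$animal_id[1L],
           " lacks a baseline row (step_index 0, injected volume 0)")
    }
  }
  if (!"corrected_additional_iav_l" %in% names(raw)) {
    raw$corrected_additional_iav_l <- unsplit(
      lapply(split(raw, raw$animal_id), function(d) {
        cumulative_corrected_iav(d$step_index, d$injected_volume_l,
                                 pmax(d$iap_cmh2o, 0))
      }), raw$animal_id)
  }
  raw
}

#' Read generator configuration from YAML
#'
#' Reads a YAML file with a `schema_version` key and any subset of the
#' [cohort_config()] fields; unspecified fields keep their defaults. The
#' mean IAP parameters may be given as a `iap_params_mean: {v:, k:, p:}`
#' mapping.
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version)) {
    stop("config file lacks a schema_version key")
  }
  y$schema_version <- NULL
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$iap_params_mean)) {
    y$iap_params_mean <- as_exp_params(y$iap_params_mean)
  }
  do.call(cohort_config, y)
}

#' Run the full pressure-volume analysis pipeline
#'
#' End-to-end orchestration: per animal, recompute Boyle-corrected
#' cumulative volumes, fit the requested pressure-volume model(s) to both
#' the IAP and the peak-airway-pressure curves, and (when both models are
#' requested) pick the winner by RMS; at cohort level, average the
#' exponential parameters into mean curves, run the pooled transmission
#' regression, build the grade table from the mean curves, and tabulate
#' compliance curves. Optionally writes all results to an output
#' directory as CSV plus a machine-readable JSON summary that records the
#' constants, options and seeds used; two runs with identical inputs and
#' options produce byte-identical summaries.
#'
#' @param cohort A `pv_cohort`, a steps data frame, or a path to a cohort
#'   CSV.
#' @param models `"both"`, `"exponential"`, or `"venegas"`.
#' @param delta_volume Added volume for the grade table, litres.
#' @param baseline_iap_mmhg,grade_thresholds_mmhg Passed to
#'   [grade_table()].
#' @param out_dir Optional output directory (created if needed).
#' @param seed Seed recorded in the summary and passed to the fits.
#' @return A list of class `"pv_report"`: `fits` (per animal/curve/model
#'   data frame), `winners`, `mean_iap_params`, `mean_ppaw_params`,
#'   `transmission`, `grade_table`, `compliance`, `options`.
#' @export
pv_report <- function(cohort, models = c("both", "exponential", "venegas"),
                      delta_volume = 0.5, baseline_iap_mmhg = 3.7,
                      grade_thresholds_mmhg = c(12, 16, 21, 26),
                      out_dir = NULL, seed = 1L) {
  models <- match.arg(models)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  steps <- if (inherits(cohort, "pv_cohort")) cohort$steps else cohort
  stopifnot(is.data.frame(steps))
  if (!"corrected_additional_iav_l" %in% names(steps)) {
    steps$corrected_additional_iav_l <- unsplit(
      lapply(split(steps, steps$animal_id), function(d) {
        d <- d[order(d$step_index), ]
        cumulative_corrected_iav(d$step_index, d$injected_volume_l,
                                 pmax(d$iap_cmh2o, 0))
      }), steps$animal_id)
  }
  model_list <- if (models == "both") c("exponential", "venegas") else models

  by_animal <- split(steps, steps$animal_id)
  if (!any(vapply(by_animal, nrow, integer(1)) >= 4L)) {
    stop("need at least one animal with >= 4 inflation steps")
  }

  fit_rows <- list(); fit_objs <- list()
  for (id in names(by_animal)) {
    d <- by_animal[[id]][order(by_animal[[id]]$step_index), ]
    vol <- cumulative_corrected_iav(d$step_index, d$injected_volume_l,
                                    pmax(d$iap_cmh2o, 0))
    for (curve in c("iap", "ppaw")) {
      pres <- if (curve == "iap") d$iap_cmh2o else d$ppaw_cmh2o
      for (mod in model_list) {
        fit <- tryCatch(
          pv_fit(pres, vol, model = mod, seed = seed),
          error = function(e) {
            stop("fit failed for animal ", id, ", ", curve, " curve (",
                 mod, "): ", conditionMessage(e))
          })
        fit_objs[[paste(id, curve, mod, sep = ".")]] <- fit
        pr <- as.list(fit$coefficients)
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          animal_id = id, curve_type = curve, model_name = mod,
          v = pr$v %||% NA_real_, k = pr$k %||% NA_real_,
          p = pr$p %||% NA_real_, a = pr$a %||% NA_real_,
          b = pr$b %||% NA_real_, c = pr$c %||% NA_real_,
          d = pr$d %||% NA_real_,
          rss = fit$rss, rms = fit$rms, n_points = fit$n,
          converged = fit$converged, stringsAsFactors = FALSE)
      }
    }
  }
  fits <- do.call(rbind, fit_rows)
  rownames(fits) <- NULL

  winners <- NULL
  if (length(model_list) > 1L) {
    winners <- do.call(rbind, lapply(names(by_animal), function(id) {
      do.call(rbind, lapply(c("iap", "ppaw"), function(curve) {
        cmp <- compare_pv_fits(lapply(model_list, function(m) {
          fit_objs[[paste(id, curve, m, sep = ".")]]
        }))
        data.frame(animal_id = id, curve_type = curve,
                   winner = cmp$winner$model,
                   rms_margin = cmp$ranking$rms[2L] - cmp$ranking$rms[1L],
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(winners) <- NULL
  }

  mean_iap <- mean_ppaw <- gtab <- NULL
  if ("exponential" %in% model_list) {
    mean_iap <- mean_exp_params(lapply(names(by_animal), function(id) {
      fit_objs[[paste(id, "iap", "exponential", sep = ".")]]
    }))
    mean_ppaw <- mean_exp_params(lapply(names(by_animal), function(id) {
      fit_objs[[paste(id, "ppaw", "exponential", sep = ".")]]
    }))
    gtab <- grade_table(mean_iap, mean_ppaw,
                        baseline_iap_mmhg = baseline_iap_mmhg,
                        grade_thresholds_mmhg = grade_thresholds_mmhg,
                        delta_volume = delta_volume)
  }

  deltas <- cohort_deltas(steps)
  trans <- if (!is.null(deltas) && nrow(deltas) >= 3L) {
    transmission_regression(deltas$delta_iap, deltas$delta_ppaw)
  } else NULL
  per_animal_slopes <- if (!is.null(deltas)) {
    do.call(rbind, lapply(split(deltas, deltas$animal_id), function(d) {
      if (nrow(d) < 3L || stats::sd(d$delta_iap) == 0) return(NULL)
      f <- stats::lm(delta_ppaw ~ delta_iap, data = d)
      data.frame(animal_id = d$animal_id[1L],
                 slope = unname(stats::coef(f)[2L]),
                 intercept = unname(stats::coef(f)[1L]),
                 n = nrow(d), stringsAsFactors = FALSE)
    }))
  } else NULL
  if (!is.null(per_animal_slopes)) rownames(per_animal_slopes) <- NULL

  compliance <- NULL
  if (!is.null(mean_iap)) {
    vgrid <- seq(0, max(steps$corrected_additional_iav_l), length.out = 50)
    pgrid <- exp_pressure(vgrid, mean_iap)
    compliance <- data.frame(
      additional_iav_l = vgrid,
      iap_cmh2o = pgrid,
      cab_ml_per_cmh2o = 1000 * exp_compliance(pgrid, mean_iap))
    if (!is.null(mean_ppaw)) {
      pp <- exp_pressure(vgrid, mean_ppaw)
      compliance$crs_ml_per_cmh2o <- crs_dynamic(
        steps$tidal_volume_ml[1L], pp, steps$peep_cmh2o[1L])
    }
  }

  report <- structure(list(
    fits = fits, winners = winners,
    mean_iap_params = mean_iap, mean_ppaw_params = mean_ppaw,
    transmission = trans, per_animal_slopes = per_animal_slopes,
    grade_table = gtab, compliance = compliance, deltas = deltas,
    steps = steps,
    options = list(models = models, delta_volume = delta_volume,
                   baseline_iap_mmhg = baseline_iap_mmhg,
                   grade_thresholds_mmhg = grade_thresholds_mmhg,
                   seed = as.integer(seed),
                   cmh2o_per_mmhg = CMH2O_PER_MMHG,
                   atmosphere_cmh2o = ATMOSPHERE_CMH2O)
  ), class = "pv_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Serialise a pv_report to CSV files plus a deterministic JSON summary.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(report$steps, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  if (!is.null(report$grade_table)) {
    utils::write.csv(as.data.frame(report$grade_table),
                     file.path(out_dir, "grade_table.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$transmission)) {
    tr <- report$transmission
    utils::write.csv(
      data.frame(intercept = tr$intercept, slope = tr$slope,
                 r_squared = tr$r_squared, p_value = tr$p_value,
                 n_points = tr$n_points),
      file.path(out_dir, "transmission.csv"), row.names = FALSE)
  }
  summary <- list(
    options = report$options,
    comparison_performed = !is.null(report$winners),
    winners = report$winners,
    mean_iap_params = as.list(unclass(report$mean_iap_params)),
    mean_ppaw_params = as.list(unclass(report$mean_ppaw_params)),
    transmission = if (!is.null(report$transmission)) {
      report$transmission[c("intercept", "slope", "r_squared",
                            "p_value", "n_points")]
    }
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pv_report <- function(x, ...) {
  cat("Pressure-volume pipeline report\n")
  cat(sprintf("  %d animals, %d fitted curves (models: %s)\n",
              length(unique(x$fits$animal_id)), nrow(x$fits),
              x$options$models))
  if (!is.null(x$winners)) {
    tab <- table(x$winners$winner[x$winners$curve_type == "iap"])
    cat("  IAP-curve winners by RMS: ",
        paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  } else {
    cat("  model comparison not performed (single model requested)\n")
  }
  if (!is.null(x$mean_iap_params)) {
    m <- x$mean_iap_params
    cat(sprintf("  mean IAP curve: v=%.3f k=%.3f p=%.3f\n",
                m[["v"]], m[["k"]], m[["p"]]))
  }
  if (!is.null(x$transmission)) print(x$transmission)
  if (!is.null(x$grade_table)) print(x$grade_table)
  invisible(x)
}
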