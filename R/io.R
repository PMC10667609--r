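#' Write a simulated cohort to disk
#'
#' Writes the three observation tables and the recruit parameters in the
#' plain-text exchange formats the pipeline reads back: `growth.csv`
#' (tank_id, treatment_temp, treatment_food, age_days, length_mm),
#' `survival.csv` (fish_id, tank_id, treatment_temp, treatment_food,
#' entry_day, exit_day, event), `clutch.csv` (tank_id, treatment_temp,
#' treatment_food, day, female_length_mm, egg_count) and `recruits.json`
#' (f_g, juvenile_logsize_mean, juvenile_logsize_sd).
#'
#' @param cohort A `cohort_data` object from [simulate_experiment()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("growth.csv", "survival.csv", "clutch.csv",
                               "recruits.json"))
  utils::write.csv(cohort$growth[, c("tank_id", "treatment_temp",
                                     "treatment_food", "age_days",
                                     "length_mm")],
                   paths[1], row.names = FALSE)
  utils::write.csv(cohort$survival[, c("fish_id", "tank_id",
                                       "treatment_temp", "treatment_food",
                                       "entry_day", "exit_day", "event")],
                   paths[2], row.names = FALSE)
  utils::write.csv(cohort$clutch[, c("tank_id", "treatment_temp",
                                     "treatment_food", "day",
                                     "female_length_mm", "egg_count")],
                   paths[3], row.names = FALSE)
  jsonlite::write_json(unclass(cohort$recruits), paths[4],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

add_treatment_key <- function(df) {
  df$treatment <- mapply(treatment_key, df$treatment_temp, df$treatment_food,
                         USE.NAMES = FALSE)
  df
}

#' Read cohort tables back from disk
#'
#' Reads `growth.csv`, `survival.csv`, `clutch.csv` and `recruits.json`
#' written by [write_cohort()] (or hand-prepared in the same schema) and
#' restores the canonical treatment keys.
#'
#' @param dir Directory containing the files.
#' @return A `cohort_data`-shaped list (without generator truth or config).
#' @export
read_cohort <- function(dir) {
  growth <- add_treatment_key(
    utils::read.csv(file.path(dir, "growth.csv"), stringsAsFactors = FALSE))
  survival <- add_treatment_key(
    utils::read.csv(file.path(dir, "survival.csv"), stringsAsFactors = FALSE))
  clutch <- add_treatment_key(
    utils::read.csv(file.path(dir, "clutch.csv"), stringsAsFactors = FALSE))
  rc <- jsonlite::read_json(file.path(dir, "recruits.json"),
                            simplifyVector = TRUE)
  structure(list(growth = growth, survival = survival, clutch = clutch,
                 recruits = recruit_params(rc$f_g, rc$juvenile_logsize_mean,
                                           rc$juvenile_logsize_sd)),
            class = "cohort_data")
}

#' Write posterior draws and run metadata
#'
#' One CSV row per retained draw (plus the chain index) and a JSON
#' metadata file holding the schedule, seed and split-R-hat values.
#'
#' @param fit A `vb_posterior` from [fit_growth()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_posterior <- function(fit, dir) {
  stopifnot(inherits(fit, "vb_posterior"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws_path <- file.path(dir, "posterior.csv")
  meta_path <- file.path(dir, "run-metadata.json")
  utils::write.csv(cbind(chain = fit$chain, as.data.frame(fit$draws)),
                   draws_path, row.names = FALSE)
  jsonlite::write_json(list(
    schedule = unclass(fit$config), rhat = as.list(fit$rhat),
    converged = fit$converged, treatments = fit$treatments,
    tanks = fit$tanks$tank_id), meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(draws_path, meta_path))
}

#' Write growth credibility bands to CSV
#'
#' @param bands A `growth_band` data.frame from [posterior_growth_bands()].
#' @param path Output CSV path (treatment, age, mean, lo, hi).
#' @export
write_bands <- function(bands, path) {
  utils::write.csv(as.data.frame(bands), path, row.names = FALSE)
  invisible(path)
}

vitals_to_list <- function(v) {
  list(s = list(intercept = v$s$intercept, slope = v$s$slope),
       growth = list(l_inf = v$growth_params[["l_inf"]],
                     k = v$growth_params[["k"]],
                     t0 = v$growth_params[["t0"]], sd_g = v$sd_g),
       f_p = list(intercept = v$f_p$intercept, slope = v$f_p$slope),
       f_n = list(a = v$f_n$a, b = v$f_n$b),
       recruits = unclass(v$recruits), rho = v$rho)
}

#' Write per-treatment vital rates to JSON
#'
#' @param vitals Named list of [vital_rates()] bundles.
#' @param path Output JSON path.
#' @export
write_vitals <- function(vitals, path) {
  jsonlite::write_json(lapply(vitals, vitals_to_list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-treatment demographic estimates to JSON
#'
#' @param demography Named list of `demographic_estimates`.
#' @param path Output JSON path.
#' @param grid Optional [build_grid()] grid whose spec is recorded.
#' @export
write_demography <- function(demography, path, grid = NULL) {
  out <- lapply(demography, function(d) {
    list(lambda = d$lambda, R0 = d$R0, T = d$T, converged = d$converged)
  })
  if (!is.null(grid)) {
    out$grid <- list(L = grid$L, U = grid$U, n_mesh = grid$n)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write bootstrap replicates and summary
#'
#' `bootstrap.csv` holds one row per treatment and replicate (lambda, T,
#' failed flag); `bootstrap-summary.json` the medians, percentile CIs and
#' the pairwise CI-overlap significance matrices.
#'
#' @param results Named list of `bootstrap_result` objects from
#'   [bootstrap_demography()].
#' @param dir Output directory.
#' @export
write_bootstrap <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(treatment = r$treatment, replicate = seq_len(r$n_boot),
               lambda = r$lambda, T = r$T, failed = r$failed,
               stringsAsFactors = FALSE)
  }))
  csv_path <- file.path(dir, "bootstrap.csv")
  utils::write.csv(rows, csv_path, row.names = FALSE)
  keys <- names(results)
  sig <- function(q) {
    m <- matrix(NA, length(keys), length(keys),
                dimnames = list(keys, keys))
    for (i in keys) for (j in keys) if (i != j) {
      m[i, j] <- compare_by_ci(results[[i]], results[[j]], q)
    }
    m
  }
  summ <- list(
    treatments = lapply(results, function(r) list(
      median_lambda = r$median_lambda, ci_lambda = r$ci_lambda,
      median_T = r$median_T, ci_T = r$ci_T, n_failed = r$n_failed)),
    significant_lambda = sig("lambda"), significant_T = sig("T"))
  json_path <- file.path(dir, "bootstrap-summary.json")
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

#' Write a sensitivity report to CSV
#'
#' @param report A `sensitivity_report` (or named list of them, one per
#'   treatment).
#' @param path Output CSV path.
#' @export
write_sensitivity <- function(report, path) {
  if (inherits(report, "sensitivity_report")) report <- list(all = report)
  rows <- do.call(rbind, lapply(names(report), function(trt) {
    cbind(treatment = trt, as.data.frame(report[[trt]]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
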