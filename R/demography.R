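#' Point-estimate demography for one treatment
#'
#' Assembles the kernels from a vital-rate bundle and returns lambda, R0,
#' generation time and the eigen-structure.
#'
#' @param vitals A [vital_rates()] bundle.
#' @param grid An [build_grid()] grid.
#' @param eviction Eviction handling for the growth kernel.
#' @return A `demographic_estimates` object.
#' @export
treatment_demography <- function(vitals, grid,
                                 eviction = c("renormalize", "truncate")) {
  k <- assemble_kernels(grid, vitals, eviction = match.arg(eviction))
  generation_time(k, asymptotic_lambda(k))
}

boot_ci <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(c(NA_real_, NA_real_))
  stats::quantile(x, c(0.025, 0.975), names = FALSE)
}

#' Bootstrap uncertainty for lambda and generation time
#'
#' Propagates growth-posterior and vital-rate sampling uncertainty into
#' the demographic estimates. Per replicate and treatment: one posterior
#' draw of (L_inf, K, t0) is sampled with replacement; the survival and
#' clutch tables are case-resampled with replacement at the record level
#' (or whole tanks, with `resample = "tanks"`); the survival logistic and
#' Poisson fecundity are refitted on the resampled data with the sampled
#' growth parameters; the IPM is solved and lambda and T recorded. The
#' reproduction-probability midpoint (an observed maturity constant), the
#' recruit parameters, the growth residual sd and the grid stay fixed.
#' Replicates whose refits degenerate or whose kernels are invalid are
#' recorded as failures and excluded from the percentile intervals; more
#' than 10% failures is a hard error.
#'
#' @param fit A `vb_posterior` from [fit_growth()].
#' @param cohort A `cohort_data` (simulated or read from disk).
#' @param maturity_length Named vector of maturity lengths (mm) per
#'   treatment; defaults to the cohort's configuration when present.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param treatments Treatment keys to process.
#' @param n_mesh Mesh count of the IPM grid.
#' @param rho Female fraction.
#' @param steepness Reproduction-probability steepness.
#' @param mode Survival fitting mode.
#' @param eviction Growth-kernel eviction handling.
#' @param resample `"records"` (case resampling) or `"tanks"` (block
#'   bootstrap over tanks).
#' @param resample_data If `FALSE`, only the growth-parameter draw varies
#'   between replicates (used to isolate posterior uncertainty).
#' @return A named list (per treatment) of `bootstrap_result` objects:
#'   replicate vectors `lambda` and `T` (NA where failed), `failed`
#'   logical vector, percentile `ci_lambda`/`ci_T`, medians, and the seed.
#' @export
bootstrap_demography <- function(fit, cohort, maturity_length = NULL,
                                 n_boot = 1000, seed = 1,
                                 treatments = fit$treatments, n_mesh = 400,
                                 rho = 0.5, steepness = 50,
                                 mode = "per_step",
                                 eviction = "renormalize",
                                 resample = c("records", "tanks"),
                                 resample_data = TRUE) {
  resample <- match.arg(resample)
  stopifnot(inherits(fit, "vb_posterior"), inherits(cohort, "cohort_data"))
  if (is.null(maturity_length)) {
    if (is.null(cohort$config)) {
      stop("maturity_length must be given when the cohort carries no config",
           call. = FALSE)
    }
    maturity_length <- stats::setNames(cohort$config$treatments$maturity_length,
                                       cohort$config$treatments$treatment)
  }
  set.seed(as.integer(seed))
  out <- list()
  for (trt in treatments) {
    draws <- treatment_draws(fit, trt)
    point <- posterior_point(fit, trt)
    growth_trt <- cohort$growth[cohort$growth$treatment == trt, ]
    surv_trt <- cohort$survival[cohort$survival$treatment == trt, ]
    clutch_trt <- cohort$clutch[cohort$clutch$treatment == trt, ]
    grid <- default_grid(point, growth_trt, n_mesh)
    sd_g <- growth_residual_sd(fit, trt)
    f_p <- reproduction_probability(log(maturity_length[[trt]]), steepness)
    tanks <- unique(surv_trt$tank_id)

    lam <- rep(NA_real_, n_boot)
    gen <- rep(NA_real_, n_boot)
    failed <- logical(n_boot)
    for (r in seq_len(n_boot)) {
      p_r <- as_vb_params(draws[sample.int(nrow(draws), 1), ])
      if (resample_data) {
        if (resample == "records") {
          s_r <- surv_trt[sample.int(nrow(surv_trt), nrow(surv_trt),
                                     replace = TRUE), ]
          c_r <- clutch_trt[sample.int(nrow(clutch_trt), nrow(clutch_trt),
                                       replace = TRUE), ]
        } else {
          tk <- sample(tanks, length(tanks), replace = TRUE)
          s_r <- do.call(rbind, lapply(tk, function(t)
            surv_trt[surv_trt$tank_id == t, ]))
          c_r <- do.call(rbind, lapply(tk, function(t)
            clutch_trt[clutch_trt$tank_id == t, ]))
        }
      } else {
        s_r <- surv_trt
        c_r <- clutch_trt
      }
      est <- tryCatch({
        if (p_r[["k"]] <= 0 || p_r[["l_inf"]] <= 0) {
          stop("non-positive growth draw")
        }
        s_fit <- suppressWarnings(
          fit_survival_logistic(kaplan_meier(s_r), p_r, mode = mode))
        f_n <- fit_fecundity(c_r)
        vit <- vital_rates(s_fit, p_r, sd_g, f_p, f_n, cohort$recruits, rho)
        k <- assemble_kernels(grid, vit, eviction = eviction)
        generation_time(k, asymptotic_lambda(k))
      }, error = function(e) NULL)
      if (is.null(est) || !is.finite(est$lambda) || !is.finite(est$T)) {
        failed[r] <- TRUE
      } else {
        lam[r] <- est$lambda
        gen[r] <- est$T
      }
    }
    if (mean(failed) > 0.10) {
      stop(sprintf("treatment %s: %.0f%% of bootstrap replicates failed; ",
                   trt, 100 * mean(failed)),
           "inputs too fragile", call. = FALSE)
    }
    out[[trt]] <- structure(list(
      treatment = trt, lambda = lam, T = gen, failed = failed,
      n_boot = as.integer(n_boot), n_failed = sum(failed),
      ci_lambda = boot_ci(lam), ci_T = boot_ci(gen),
      median_lambda = stats::median(lam, na.rm = TRUE),
      median_T = stats::median(gen, na.rm = TRUE),
      seed = as.integer(seed)), class = "bootstrap_result")
  }
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%s: lambda %.5f [%.5f, %.5f], T %.1f [%.1f, %.1f] (%d/%d ok)\n",
              x$treatment, x$median_lambda, x$ci_lambda[1], x$ci_lambda[2],
              x$median_T, x$ci_T[1], x$ci_T[2],
              x$n_boot - x$n_failed, x$n_boot))
  invisible(x)
}

#' Compare two treatments by bootstrap CI overlap
#'
#' Declares a difference significant exactly when the two closed 95%
#' percentile intervals are disjoint; intervals touching at an endpoint
#' overlap, hence are not significant.
#'
#' @param a,b `bootstrap_result` objects.
#' @param quantity `"lambda"` or `"T"`.
#' @return Logical scalar.
#' @export
compare_by_ci <- function(a, b, quantity = c("lambda", "T")) {
  quantity <- match.arg(quantity)
  ci_a <- if (quantity == "lambda") a$ci_lambda else a$ci_T
  ci_b <- if (quantity == "lambda") b$ci_lambda else b$ci_T
  if (any(!is.finite(c(ci_a, ci_b)))) {
    stop("confidence intervals unavailable for the requested quantity",
         call. = FALSE)
  }
  (ci_a[1] > ci_b[2]) || (ci_b[1] > ci_a[2])
}

perturb_vitals <- function(vitals, param, value) {
  v <- vitals
  switch(param,
    s_intercept = { v$s$intercept <- value },
    s_slope = { v$s$slope <- value },
    fp_midpoint = {
      steep <- v$f_p$slope
      v$f_p <- reproduction_probability(value, steep)
    },
    fp_steepness = {
      zmat <- -v$f_p$intercept / v$f_p$slope
      v$f_p <- reproduction_probability(zmat, value)
    },
    fec_a = { v$f_n$a <- value },
    fec_b = { v$f_n$b <- value },
    f_g = { v$recruits$f_g <- value },
    rho = { v$rho <- value },
    juvenile_mean = { v$recruits$juvenile_logsize_mean <- value },
    juvenile_sd = { v$recruits$juvenile_logsize_sd <- value },
    sd_g = { v$sd_g <- value },
    l_inf = { v$growth_params[["l_inf"]] <- value },
    k = { v$growth_params[["k"]] <- value },
    stop("unknown parameter: ", param, call. = FALSE))
  v
}

vital_param_value <- function(vitals, param) {
  switch(param,
    s_intercept = vitals$s$intercept,
    s_slope = vitals$s$slope,
    fp_midpoint = -vitals$f_p$intercept / vitals$f_p$slope,
    fp_steepness = vitals$f_p$slope,
    fec_a = vitals$f_n$a,
    fec_b = vitals$f_n$b,
    f_g = vitals$recruits$f_g,
    rho = vitals$rho,
    juvenile_mean = vitals$recruits$juvenile_logsize_mean,
    juvenile_sd = vitals$recruits$juvenile_logsize_sd,
    sd_g = vitals$sd_g,
    l_inf = vitals$growth_params[["l_inf"]],
    k = vitals$growth_params[["k"]])
}

sens_solve <- function(vitals, grid, eviction) {
  k <- assemble_kernels(grid, vitals, eviction = eviction)
  lam <- asymptotic_lambda(k)
  T_ <- tryCatch(generation_time(k, lam)$T, error = function(e) NA_real_)
  c(lambda = lam$lambda, T = T_)
}

#' Vital-rate sensitivity analysis of lambda and generation time
#'
#' Central finite-difference sensitivities of lambda and T to a relative
#' perturbation of each scalar vital-rate parameter, with elasticities
#' \eqn{(\theta / \lambda) \partial \lambda / \partial \theta}. A
#' perturbation that would push a probability above 1 is clamped to 1 and
#' flagged; the actual perturbation span is used in the denominator.
#' Parameters whose baseline value is 0 are perturbed additively by
#' `delta` (elasticity 0 by definition).
#'
#' @param vitals A [vital_rates()] bundle.
#' @param grid An [build_grid()] grid.
#' @param delta Relative perturbation (> 0); default 0.01.
#' @param parameters Subset of parameters to perturb (default: all
#'   thirteen scalar vital-rate parameters).
#' @param eviction Growth-kernel eviction handling.
#' @return A data.frame of class `sensitivity_report` with columns
#'   `parameter`, `theta`, `delta`, `d_lambda`, `d_T`,
#'   `elasticity_lambda`, `elasticity_T`, `clamped`.
#' @export
sensitivity_analysis <- function(vitals, grid, delta = 0.01,
                                 parameters = c("s_intercept", "s_slope",
                                                "fp_midpoint", "fp_steepness",
                                                "fec_a", "fec_b", "f_g",
                                                "rho", "juvenile_mean",
                                                "juvenile_sd", "sd_g",
                                                "l_inf", "k"),
                                 eviction = "renormalize") {
  stopifnot(delta > 0)
  base <- sens_solve(vitals, grid, eviction)
  rows <- lapply(parameters, function(p) {
    theta <- vital_param_value(vitals, p)
    if (!is.finite(theta)) {
      # e.g. the midpoint of a flat reproduction curve is undefined
      return(data.frame(parameter = p, theta = theta, delta = delta,
                        d_lambda = NA_real_, d_T = NA_real_,
                        elasticity_lambda = NA_real_,
                        elasticity_T = NA_real_, clamped = FALSE,
                        stringsAsFactors = FALSE))
    }
    if (theta == 0) {
      lo <- -delta; hi <- delta
    } else {
      lo <- theta * (1 - delta); hi <- theta * (1 + delta)
    }
    clamped <- FALSE
    if (p %in% c("f_g", "rho")) {
      if (hi > 1) { hi <- 1; clamped <- TRUE }
      if (lo < 0) { lo <- 0; clamped <- TRUE }
    }
    span <- hi - lo
    if (span == 0) {
      return(data.frame(parameter = p, theta = theta, delta = delta,
                        d_lambda = 0, d_T = 0, elasticity_lambda = 0,
                        elasticity_T = 0, clamped = clamped,
                        stringsAsFactors = FALSE))
    }
    up <- sens_solve(perturb_vitals(vitals, p, hi), grid, eviction)
    dn <- sens_solve(perturb_vitals(vitals, p, lo), grid, eviction)
    d_lam <- (up[["lambda"]] - dn[["lambda"]]) / span
    d_T <- (up[["T"]] - dn[["T"]]) / span
    data.frame(parameter = p, theta = theta, delta = delta,
               d_lambda = d_lam, d_T = d_T,
               elasticity_lambda = theta / base[["lambda"]] * d_lam,
               elasticity_T = if (is.finite(base[["T"]]))
                 theta / base[["T"]] * d_T else NA_real_,
               clamped = clamped, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("sensitivity_report", "data.frame"))
}
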