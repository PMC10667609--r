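# multivariate normal draws that tolerate exactly-singular covariance
# (the zero-noise test configuration sets Sigma = 0)
rmvnorm_psd <- function(n, sigma) {
  d <- nrow(sigma)
  if (all(sigma == 0)) return(matrix(0, n, d))
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < -1e-10 * max(abs(e$values))) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  a <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), d)
  matrix(stats::rnorm(n * d), n, d) %*% t(a)
}

round_half_mm <- function(x) round(x * 2) / 2

#' Simulate a synthetic 2x2 temperature-by-feeding cohort experiment
#'
#' Generates the three observation tables the analysis pipeline consumes,
#' with the statistical structure the downstream model assumes:
#'
#' * **growth**: per tank, a deviation vector drawn from the multivariate
#'   normal tank random effect is added to the treatment-level Von
#'   Bertalanffy parameters; at each measurement day a cross-sectional
#'   subsample of fish (uniform count within `measured_per_day`) is
#'   measured as the tank curve plus Normal residual noise, recorded at
#'   0.5 mm precision (rounding applied after noise). Fish are not
#'   individually identified, mirroring population-level growth monitoring.
#' * **survival**: every fish enters the risk set at `entry_day`; death
#'   times are drawn from the treatment's constant daily hazard and
#'   right-censored at `end_day`.
#' * **clutch**: from the treatment's maturity age onwards, daily clutch
#'   counts are drawn as Poisson with log mean `fec_a + fec_b * log(L)`,
#'   where `L` is the treatment growth curve's reference length at that
#'   day. Layout `"per_observation"` records one observed female per tank
#'   per day; `"tank_day"` aggregates `round(rho * fish_per_tank)` females
#'   and records the rounded per-female mean.
#'
#' Identical `(config, seed)` pairs give identical output.
#'
#' @param config A [default_config()]-shaped `cohort_config`.
#' @param seed Integer seed; overrides `config$seed`.
#' @return An object of class `cohort_data`: a list with data.frames
#'   `growth` (tank_id, treatment, treatment_temp, treatment_food,
#'   age_days, length_mm), `survival` (fish_id, tank_id, treatment,
#'   treatment_temp, treatment_food, entry_day, exit_day, event), `clutch`
#'   (tank_id, treatment, treatment_temp, treatment_food, day,
#'   female_length_mm, egg_count), the `recruits` parameter list, the
#'   per-tank true parameters (`tank_truth`), and the `config`/`seed` used.
#' @examples
#' cohort <- simulate_experiment(default_config(), seed = 1)
#' table(cohort$growth$treatment, cohort$growth$age_days)[, 1:3]
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  validate_config(config)
  set.seed(as.integer(seed))
  tr <- config$treatments
  st <- config$sigma_tank
  sigma <- ranef_cov(st$sd_l_inf, st$sd_k, st$sd_t0, st$r1, st$r2, st$r3)

  growth <- list(); surv <- list(); clutch <- list(); truth <- list()
  fish_counter <- 0L
  for (i in seq_len(nrow(tr))) {
    trt <- tr[i, ]
    key <- trt$treatment
    for (tk in seq_len(trt$n_tanks)) {
      tank_id <- sprintf("%s_t%d", key, tk)
      eps <- drop(rmvnorm_psd(1, sigma))
      p_tank <- vb_params(trt$l_inf + eps[1], trt$k + eps[2], trt$t0 + eps[3])
      truth[[tank_id]] <- data.frame(
        tank_id = tank_id, treatment = key,
        l_inf = p_tank[["l_inf"]], k = p_tank[["k"]], t0 = p_tank[["t0"]],
        stringsAsFactors = FALSE)

      # cross-sectional length measurements
      for (day in config$measurement_days) {
        m <- if (config$measured_per_day[1] == config$measured_per_day[2]) {
          config$measured_per_day[1]
        } else {
          sample(seq(config$measured_per_day[1], config$measured_per_day[2]), 1)
        }
        m <- min(m, trt$fish_per_tank)
        len <- vb_length(p_tank, day) + stats::rnorm(m, 0, config$sigma_obs)
        len <- pmax(round_half_mm(len), 0.5)
        growth[[length(growth) + 1L]] <- data.frame(
          tank_id = tank_id, treatment = key,
          treatment_temp = trt$temperature, treatment_food = trt$food,
          age_days = as.integer(day), length_mm = len,
          stringsAsFactors = FALSE)
      }

      # survival from entry_day under a constant daily hazard
      n_fish <- trt$fish_per_tank
      ids <- sprintf("f%05d", fish_counter + seq_len(n_fish))
      fish_counter <- fish_counter + n_fish
      if (trt$hazard > 0) {
        death_day <- config$entry_day + ceiling(stats::rexp(n_fish, trt$hazard))
      } else {
        death_day <- rep(Inf, n_fish)
      }
      event <- ifelse(death_day <= config$end_day, "death", "censored")
      exit <- pmin(death_day, config$end_day)
      surv[[length(surv) + 1L]] <- data.frame(
        fish_id = ids, tank_id = tank_id, treatment = key,
        treatment_temp = trt$temperature, treatment_food = trt$food,
        entry_day = as.integer(config$entry_day),
        exit_day = as.integer(exit), event = event,
        stringsAsFactors = FALSE)

      # daily clutch observations after maturity, referenced to the
      # treatment-level growth curve (females not individually tracked)
      days <- seq(ceiling(trt$maturity_age), config$end_day)
      if (length(days) > 0) {
        p_trt <- vb_params(trt$l_inf, trt$k, trt$t0)
        ref_len <- vb_length(p_trt, days)
        mu <- exp(trt$fec_a + trt$fec_b * log(ref_len))
        if (config$clutch_layout == "per_observation") {
          eggs <- stats::rpois(length(days), mu)
        } else {
          n_f <- max(1L, round(config$rho * trt$fish_per_tank))
          totals <- stats::rpois(length(days), n_f * mu)
          eggs <- round(totals / n_f)
        }
        clutch[[length(clutch) + 1L]] <- data.frame(
          tank_id = tank_id, treatment = key,
          treatment_temp = trt$temperature, treatment_food = trt$food,
          day = as.integer(days),
          female_length_mm = round_half_mm(ref_len),
          egg_count = as.integer(eggs),
          stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(
    growth = do.call(rbind, growth),
    survival = do.call(rbind, surv),
    clutch = do.call(rbind, clutch),
    recruits = recruit_params(config$recruits$f_g,
                              config$recruits$juvenile_logsize_mean,
                              config$recruits$juvenile_logsize_sd),
    tank_truth = do.call(rbind, truth),
    config = config,
    seed = as.integer(seed)
  ), class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("Synthetic cohort data\n")
  cat(sprintf("  growth:   %d length-at-age records\n", nrow(x$growth)))
  cat(sprintf("  survival: %d fish\n", nrow(x$survival)))
  cat(sprintf("  clutch:   %d clutch observations\n", nrow(x$clutch)))
  invisible(x)
}
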