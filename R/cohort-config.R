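#' Assemble the tank random-effect covariance matrix
#'
#' Builds the 3x3 covariance matrix of the tank-level deviations
#' (\eqn{\epsilon_{L\infty}, \epsilon_K, \epsilon_{t0}}) from its standard
#' deviations and pairwise correlations: `r1` couples L_inf and K, `r2`
#' couples L_inf and t0, `r3` couples K and t0.
#'
#' @param sd_l_inf,sd_k,sd_t0 Standard deviations (>= 0) of the three
#'   random-effect components.
#' @param r1,r2,r3 Pairwise correlations in \[-1, 1\].
#' @return A symmetric 3x3 matrix with dimnames `l_inf`, `k`, `t0`.
#' @export
ranef_cov <- function(sd_l_inf, sd_k, sd_t0, r1 = 0, r2 = 0, r3 = 0) {
  stopifnot(sd_l_inf >= 0, sd_k >= 0, sd_t0 >= 0,
            abs(r1) <= 1, abs(r2) <= 1, abs(r3) <= 1)
  s <- c(sd_l_inf, sd_k, sd_t0)
  r <- matrix(c(1, r1, r2,
                r1, 1, r3,
                r2, r3, 1), 3, 3, byrow = TRUE)
  m <- diag(s) %*% r %*% diag(s)
  dimnames(m) <- list(c("l_inf", "k", "t0"), c("l_inf", "k", "t0"))
  (m + t(m)) / 2
}

#' Default synthetic-cohort configuration
#'
#' Returns the configuration of the synthetic 2x2 temperature-by-feeding
#' medaka experiment that the package's tests and examples run on. The
#' experimental design constants (four treatments, 3/3/3 tanks plus 2 tanks
#' for `inter_20`, roughly 80 or 54 fish per treatment, measurement at days
#' 30, 45, 60, 100, 150, 200, 300 and 350 post hatching, 12-17 fish
#' measured per tank per day, survival monitored from day 60, maturity
#' ages/sizes per treatment) follow the experiment the generator emulates.
#' The remaining numeric truths (growth parameters, tank covariance, daily
#' hazards, fecundity coefficients, recruit parameters) are documented
#' synthetic choices, calibrated once so that the generated populations
#' show the canonical regime: crossed growth curves under warming, nested
#' curves under intermittent feeding, higher warm fecundity, higher warm
#' mortality, and population growth rates close to one. See the methods
#' vignette for the calibration rationale.
#'
#' @return An object of class `cohort_config`; a list with components
#'   `treatments` (per-treatment truth table), `sigma_tank` (random-effect
#'   covariance inputs), `sigma_obs` (residual length sd, mm),
#'   `measurement_days`, `measured_per_day` (inclusive range),
#'   `entry_day`/`end_day` (survival monitoring window), `recruits`
#'   (`f_g`, `juvenile_logsize_mean`, `juvenile_logsize_sd`), `rho`
#'   (female fraction), `maturity_steepness` (logistic steepness of the
#'   reproduction-probability curve, per log-length unit), `clutch_layout`
#'   and `seed`.
#' @examples
#' cfg <- default_config()
#' cfg$treatments[, c("treatment", "l_inf", "k", "maturity_age")]
#' @export
default_config <- function() {
  tr <- data.frame(
    treatment = treatment_keys(),
    stringsAsFactors = FALSE
  )
  tr <- cbind(tr, treatment_labels(tr$treatment)[, c("temperature", "food")])
  rownames(tr) <- tr$treatment
  # growth truths: warm grows faster initially but to a smaller asymptote
  # (crossed curves); intermittent feeding nests the curve below its
  # continuous counterpart
  tr$l_inf <- c(32.0, 30.0, 25.0, 23.5)
  tr$k     <- c(0.010, 0.009, 0.020, 0.018)
  tr$t0    <- c(-8, -8, 0, 0)
  # maturity schedule: first sexually mature fish per treatment
  tr$maturity_age    <- c(169.7, 186.5, 67.3, 60.0)
  tr$maturity_length <- c(26.3, 25.7, 16.8, 17.2)
  # constant daily mortality hazard from day 60; warming raises mortality,
  # intermittent feeding lowers it ("eat little die old")
  tr$hazard <- c(0.0020, 0.0012, 0.0040, 0.0025)
  # log-linear fecundity (eggs per female per day): log mean = a + b log L;
  # warm treatments lay more at a given size, intermittent slightly fewer
  tr$fec_a <- c(-4.5, -4.8, -2.7, -3.0)
  tr$fec_b <- rep(2.0, 4)
  tr$n_tanks <- c(3L, 2L, 3L, 3L)
  tr$fish_per_tank <- rep(27L, 4)

  structure(list(
    treatments = tr,
    sigma_tank = list(sd_l_inf = 0.8, sd_k = 0.0008, sd_t0 = 1.5,
                      r1 = 0.2, r2 = 0.2, r3 = 0.2),
    sigma_obs = 0.9,
    measurement_days = c(30L, 45L, 60L, 100L, 150L, 200L, 300L, 350L),
    measured_per_day = c(12L, 17L),
    entry_day = 60L,
    end_day = 350L,
    recruits = list(f_g = 6e-4,
                    juvenile_logsize_mean = log(10.5),
                    juvenile_logsize_sd = 0.12),
    rho = 0.5,
    maturity_steepness = 50,
    clutch_layout = "per_observation",
    seed = 1L
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d treatments, %d tanks, %d fish per tank\n",
              nrow(x$treatments), sum(x$treatments$n_tanks),
              x$treatments$fish_per_tank[1]))
  cat("  measurement days:", paste(x$measurement_days, collapse = ", "), "\n")
  cat(sprintf("  survival window: day %d to %d\n", x$entry_day, x$end_day))
  invisible(x)
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants of a [default_config()]-shaped
#' configuration: positive-semidefinite tank covariance, correlations in
#' \[-1, 1\], non-negative hazards, probabilities in \[0, 1\], strictly
#' increasing measurement days.
#'
#' @param config A `cohort_config`.
#' @return Invisibly `config`; errors if any invariant is violated.
#' @export
validate_config <- function(config) {
  tr <- config$treatments
  if (!all(sort(tr$treatment) == sort(treatment_keys()))) {
    stop("config must contain exactly the four canonical treatments",
         call. = FALSE)
  }
  if (any(tr$hazard < 0)) stop("hazards must be >= 0", call. = FALSE)
  st <- config$sigma_tank
  if (any(abs(c(st$r1, st$r2, st$r3)) > 1)) {
    stop("random-effect correlations must lie in [-1, 1]", call. = FALSE)
  }
  sig <- ranef_cov(st$sd_l_inf, st$sd_k, st$sd_t0, st$r1, st$r2, st$r3)
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("tank random-effect covariance is not positive semi-definite",
         call. = FALSE)
  }
  if (is.unsorted(config$measurement_days, strictly = TRUE)) {
    stop("measurement days must be strictly increasing", call. = FALSE)
  }
  rc <- config$recruits
  if (rc$f_g < 0 || rc$f_g > 1) stop("f_g must lie in [0, 1]", call. = FALSE)
  if (rc$juvenile_logsize_sd <= 0) {
    stop("juvenile log-size sd must be positive", call. = FALSE)
  }
  if (config$rho < 0 || config$rho > 1) {
    stop("female fraction rho must lie in [0, 1]", call. = FALSE)
  }
  if (config$sigma_obs < 0) stop("sigma_obs must be >= 0", call. = FALSE)
  invisible(config)
}
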