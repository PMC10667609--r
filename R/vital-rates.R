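#' Logistic curve on the log-size domain
#'
#' A two-parameter logistic function of log body size `z`,
#' \eqn{p(z) = 1 / (1 + e^{-(intercept + slope \cdot z)})}, used for the
#' size-dependent survival function `s` and the reproduction probability
#' `f_p`.
#'
#' @param intercept,slope Coefficients on the logit scale (slope per unit
#'   log length).
#' @return An object of class `logistic_curve`; evaluate with
#'   [predict_prob()].
#' @export
logistic_curve <- function(intercept, slope) {
  structure(list(intercept = as.numeric(intercept),
                 slope = as.numeric(slope)),
            class = "logistic_curve")
}

#' Evaluate a logistic curve
#'
#' @param curve A [logistic_curve()].
#' @param z Log body size (vectorized).
#' @return Probabilities in (0, 1).
#' @export
predict_prob <- function(curve, z) {
  stopifnot(inherits(curve, "logistic_curve"))
  stats::plogis(curve$intercept + curve$slope * z)
}

#' Log-linear fecundity model
#'
#' Expected clutch size (eggs per female per day) as a function of log
#' body size: `mean = exp(a + b * z)`.
#'
#' @param a Intercept on the log scale.
#' @param b Slope per unit log length.
#' @return An object of class `fecundity_model`; evaluate with
#'   [predict_eggs()].
#' @export
fecundity_model <- function(a, b) {
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = "fecundity_model")
}

#' @rdname fecundity_model
#' @param model A `fecundity_model`.
#' @param z Log body size (vectorized).
#' @export
predict_eggs <- function(model, z) {
  stopifnot(inherits(model, "fecundity_model"))
  exp(model$a + model$b * z)
}

#' Recruit parameters
#'
#' Egg-to-recruit survival (`f_g`: egg hatching probability times juvenile
#' survival to the recruit stage) and the juvenile log-size distribution
#' (`f_d`: Normal with the given mean and sd, truncated to the IPM domain
#' at kernel assembly).
#'
#' @param f_g Probability in \[0, 1\].
#' @param juvenile_logsize_mean,juvenile_logsize_sd Parameters of the
#'   recruit log-size distribution (sd > 0).
#' @return An object of class `recruit_params`.
#' @export
recruit_params <- function(f_g, juvenile_logsize_mean, juvenile_logsize_sd) {
  stopifnot(f_g >= 0, f_g <= 1, juvenile_logsize_sd > 0)
  structure(list(f_g = as.numeric(f_g),
                 juvenile_logsize_mean = as.numeric(juvenile_logsize_mean),
                 juvenile_logsize_sd = as.numeric(juvenile_logsize_sd)),
            class = "recruit_params")
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Nonparametric survival curve from individual event/censoring records,
#' together with the daily risk table (numbers at risk and deaths per day)
#' that the per-step logistic survival fit consumes. All fish enter the
#' risk set at their `entry_day`; censored fish leave it after their
#' `exit_day`. S(t) is the product over event days up to t of
#' (1 - deaths/at risk).
#'
#' @param records Data.frame with columns `entry_day`, `exit_day`, `event`
#'   (`"death"` or `"censored"`).
#' @return An object of class `km_curve`: `time` (distinct event days),
#'   `surv` (S at those days), `n_risk`, `n_event`, plus a `daily`
#'   data.frame (`day`, `n_risk`, `n_event`) covering every day from entry
#'   to the last exit, and the `entry_day`.
#' @examples
#' rec <- data.frame(entry_day = 60, exit_day = c(61, 63, 100, 100, 100),
#'                   event = c("death", "death", rep("censored", 3)))
#' km <- kaplan_meier(rec)
#' km$surv  # 0.8 then 0.6
#' @export
kaplan_meier <- function(records) {
  stopifnot(nrow(records) >= 1,
            all(c("entry_day", "exit_day", "event") %in% names(records)))
  if (any(records$exit_day < records$entry_day)) {
    stop("exit before entry in survival records", call. = FALSE)
  }
  if (length(unique(records$entry_day)) > 1) {
    stop("all records must share a common entry day", call. = FALSE)
  }
  entry <- records$entry_day[1]
  last <- max(records$exit_day)
  days <- seq(entry + 1, last)
  death_day <- records$exit_day[records$event == "death"]
  exit_any <- records$exit_day
  # at risk on day d: present after d-1, i.e. exit day >= d
  n_risk <- vapply(days, function(d) sum(exit_any >= d), 0L)
  n_event <- vapply(days, function(d) sum(death_day == d), 0L)
  keep <- n_risk > 0
  days <- days[keep]; n_risk <- n_risk[keep]; n_event <- n_event[keep]
  surv_daily <- cumprod(1 - n_event / n_risk)
  ev <- n_event > 0
  structure(list(time = days[ev], surv = surv_daily[ev],
                 n_risk = n_risk[ev], n_event = n_event[ev],
                 daily = data.frame(day = days, n_risk = n_risk,
                                    n_event = n_event,
                                    surv = surv_daily),
                 entry_day = entry),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve from day %d: %d event days, final S = %.3f\n",
              x$entry_day, length(x$time),
              if (length(x$surv)) min(x$surv) else 1))
  invisible(x)
}

#' Fit the size-dependent survival function s(z)
#'
#' Converts the Kaplan-Meier estimate into a logistic function of log body
#' size, using the fitted growth curve to map each monitored age to a
#' size. Two readings are supported:
#'
#' * `"per_step"` (default, demographically consistent with a daily-step
#'   IPM): a binomial GLM of daily survival, with the daily risk table
#'   supplying deaths and numbers at risk per day and the growth curve
#'   supplying z at each day. The fitted curve is the probability of
#'   surviving one day at size z.
#' * `"cumulative"` (literal reading): the cumulative KM survival S(t)
#'   regressed on z(t) by a quasibinomial logistic fit weighted by numbers
#'   at risk.
#'
#' Degenerate inputs (no deaths at all, or complete separation) yield a
#' flat curve at the observed mean survival with a warning rather than an
#' error.
#'
#' @param km A [kaplan_meier()] curve.
#' @param params [vb_params()] used for the age-to-size mapping.
#' @param mode `"per_step"` or `"cumulative"`.
#' @return A [logistic_curve()] (slope 0 in the degenerate fallback).
#' @export
fit_survival_logistic <- function(km, params, mode = c("per_step",
                                                       "cumulative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(km, "km_curve"))
  d <- km$daily
  if (nrow(d) == 0) stop("empty Kaplan-Meier curve", call. = FALSE)
  z <- age_to_size(params, d$day)
  flat <- function(p) {
    p <- min(max(p, 1e-12), 1 - 1e-12)
    logistic_curve(stats::qlogis(p), 0)
  }
  if (mode == "per_step") {
    if (sum(d$n_event) == 0) {
      warning("no deaths observed; returning flat survival at 1",
              call. = FALSE)
      return(flat(1 - 1e-8))
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        cbind(d$n_risk - d$n_event, d$n_event) ~ z, family = stats::binomial())),
      error = function(e) NULL)
    mean_p <- 1 - sum(d$n_event) / sum(d$n_risk)
    if (is.null(fit) || !fit$converged || any(!is.finite(stats::coef(fit)))) {
      warning("survival logistic fit degenerated; returning flat curve",
              call. = FALSE)
      return(flat(mean_p))
    }
    cf <- stats::coef(fit)
    logistic_curve(cf[[1]], cf[[2]])
  } else {
    s <- d$surv
    if (all(s == s[1])) {
      warning("cumulative survival constant; returning flat curve",
              call. = FALSE)
      return(flat(s[1]))
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm(s ~ z, family = stats::quasibinomial(),
                                  weights = d$n_risk)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(stats::coef(fit)))) {
      warning("survival logistic fit degenerated; returning flat curve",
              call. = FALSE)
      return(flat(mean(s)))
    }
    cf <- stats::coef(fit)
    logistic_curve(cf[[1]], cf[[2]])
  }
}

#' Reproduction probability f_p(z)
#'
#' Smooth step at the size at maturity: every fish is assumed to reproduce
#' once it has reached its treatment-dependent maturity size, implemented
#' as a steep logistic \eqn{f_p(z) = 1 / (1 + e^{-steepness (z - z_{mat})})}.
#'
#' @param z_mat Log length at maturity.
#' @param steepness Logistic steepness per unit log length (> 0); large
#'   values approximate a hard step while staying differentiable.
#' @return A [logistic_curve()].
#' @export
reproduction_probability <- function(z_mat, steepness = 50) {
  stopifnot(steepness > 0)
  logistic_curve(-steepness * z_mat, steepness)
}

#' Fit the fecundity function f_n(z)
#'
#' Maximum-likelihood Poisson regression (log link) of daily clutch counts
#' on log female length: `E(eggs) = exp(a + b z)`.
#'
#' @param clutch Data.frame with columns `female_length_mm` and
#'   `egg_count`.
#' @return A [fecundity_model()].
#' @export
fit_fecundity <- function(clutch) {
  stopifnot(all(c("female_length_mm", "egg_count") %in% names(clutch)))
  if (nrow(clutch) < 2 || length(unique(clutch$female_length_mm)) < 2) {
    stop("need clutch observations at >= 2 distinct sizes", call. = FALSE)
  }
  if (all(clutch$egg_count == 0)) {
    stop("all clutch counts are zero; log-link mean undefined", call. = FALSE)
  }
  z <- log(clutch$female_length_mm)
  fit <- stats::glm(clutch$egg_count ~ z, family = stats::poisson())
  cf <- stats::coef(fit)
  fecundity_model(cf[[1]], cf[[2]])
}

#' Residual growth variation for the IPM kernel
#'
#' Propagates posterior uncertainty in the growth parameters into a single
#' residual sd for the growth kernel: for each age, every retained
#' posterior draw is pushed through the growth curve to a size at t and
#' then through the one-day update to a size at t+1; the standard
#' deviation across draws of the (log, by default) size at t+1 is computed
#' per age, and the per-age sds are averaged.
#'
#' Draws predicting a non-positive length at an age cannot be mapped to
#' the log domain and are excluded at that age; an age enters the average
#' only if at least 90% of draws are valid there (short-chain posteriors
#' can carry a few stray K <= 0 draws), and at least one valid age is
#' required.
#'
#' @param fit A `vb_posterior` from [fit_growth()].
#' @param treatment Treatment key.
#' @param ages Ages (days) to average over; default 30 to 350.
#' @param scale `"log"` (sd on the log-size domain, directly usable as the
#'   kernel sd) or `"mm"`.
#' @return A single non-negative number.
#' @export
growth_residual_sd <- function(fit, treatment, ages = 30:350,
                               scale = c("log", "mm")) {
  scale <- match.arg(scale)
  d <- treatment_draws(fit, treatment)
  if (nrow(d) == 0) stop("posterior is empty", call. = FALSE)
  ek <- exp(-d[, "k"])
  # population sd so the result is invariant to duplicating draws
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  sds <- vapply(ages, function(a) {
    l_t <- d[, "l_inf"] * (1 - exp(-d[, "k"] * (a - d[, "t0"])))
    l_t1 <- l_t * ek + d[, "l_inf"] * (1 - ek)
    ok <- l_t > 0 & l_t1 > 0
    if (mean(ok) < 0.9) return(NA_real_)
    if (scale == "log") psd(log(l_t1[ok])) else psd(l_t1[ok])
  }, 0)
  sds <- sds[!is.na(sds)]
  if (length(sds) == 0) {
    stop("no age with all-positive predicted lengths", call. = FALSE)
  }
  mean(sds)
}

#' Bundle the vital rates of one treatment
#'
#' Collects the six ingredients the IPM kernel assembly needs: the
#' survival curve s, the growth parameters and residual sd for g, the
#' reproduction probability f_p, the fecundity model f_n, the recruit
#' parameters (f_g, f_d), and the female fraction rho.
#'
#' @param s A [logistic_curve()] for daily survival.
#' @param growth_params [vb_params()] of the treatment.
#' @param sd_g Residual growth sd on the log-size domain (>= 0).
#' @param f_p A [logistic_curve()] for reproduction probability.
#' @param f_n A [fecundity_model()].
#' @param recruits A [recruit_params()].
#' @param rho Female fraction in \[0, 1\] multiplying recruitment.
#' @return An object of class `vital_rates`.
#' @export
vital_rates <- function(s, growth_params, sd_g, f_p, f_n, recruits,
                        rho = 0.5) {
  stopifnot(inherits(s, "logistic_curve"), inherits(f_p, "logistic_curve"),
            inherits(f_n, "fecundity_model"),
            inherits(recruits, "recruit_params"),
            sd_g >= 0, rho >= 0, rho <= 1)
  structure(list(s = s, growth_params = as_vb_params(growth_params),
                 sd_g = sd_g, f_p = f_p, f_n = f_n, recruits = recruits,
                 rho = rho),
            class = "vital_rates")
}

#' Estimate all vital rates of one treatment from data
#'
#' Convenience constructor running the vital-rate stages in order: KM
#' survival then per-step logistic s(z); reproduction probability from the
#' maturity length; Poisson fecundity from the clutch table; growth
#' parameters and residual sd from the growth posterior.
#'
#' @param fit A `vb_posterior`.
#' @param treatment Treatment key.
#' @param survival Survival records for that treatment.
#' @param clutch Clutch observations for that treatment.
#' @param recruits A [recruit_params()].
#' @param maturity_length Length at maturity (mm).
#' @param rho Female fraction.
#' @param steepness Steepness of f_p per log-length unit.
#' @param mode Survival fitting mode, see [fit_survival_logistic()].
#' @return A [vital_rates()] object.
#' @export
estimate_vital_rates <- function(fit, treatment, survival, clutch, recruits,
                                 maturity_length, rho = 0.5, steepness = 50,
                                 mode = "per_step") {
  params <- posterior_point(fit, treatment)
  km <- kaplan_meier(survival)
  s <- fit_survival_logistic(km, params, mode = mode)
  f_p <- reproduction_probability(log(maturity_length), steepness)
  f_n <- fit_fecundity(clutch)
  sd_g <- growth_residual_sd(fit, treatment)
  vital_rates(s, params, sd_g, f_p, f_n, recruits, rho)
}
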