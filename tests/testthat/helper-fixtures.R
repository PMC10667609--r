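# Shared fixtures, built in code at test time.

# short MCMC schedule for module-level smoke/recovery tests
quick_mcmc <- function(seed = 1, ...) {
  test_mcmc_config(n_chains = 2, n_burnin = 800, n_iterations = 1600,
                   thin = 8, seed = seed, ...)
}

# growth table restricted to two treatments, to keep module fits cheap
two_treatment_growth <- function(seed = 21) {
  co <- simulate_experiment(default_config(), seed = seed)
  co$growth[co$growth$treatment %in% c("conti_20", "conti_30"), ]
}

# minimal vb_posterior carrying given treatment-level draws
fake_posterior <- function(draws, treatment = "conti_20") {
  colnames(draws) <- paste0(c("l_inf", "k", "t0"), "[", treatment, "]")
  structure(list(draws = draws, chain = rep(1L, nrow(draws)),
                 treatments = treatment),
            class = "vb_posterior")
}

# fabricated bootstrap result with given intervals
fake_boot <- function(ci_lambda, ci_T = c(1, 2), treatment = "x") {
  structure(list(treatment = treatment, lambda = numeric(0), T = numeric(0),
                 failed = logical(0), n_boot = 0L, n_failed = 0L,
                 ci_lambda = ci_lambda, ci_T = ci_T,
                 median_lambda = mean(ci_lambda), median_T = mean(ci_T),
                 seed = 1L),
            class = "bootstrap_result")
}

# size-independent vital rates (flat logistic curves, constant fecundity)
flat_vitals <- function(s, f_p, f_n, f_g, rho, params = vb_params(30, 0.02, 0),
                        sd_g = 0.05, juv_mean = 2.6, juv_sd = 0.15) {
  vital_rates(
    s = logistic_curve(stats::qlogis(s), 0),
    growth_params = params, sd_g = sd_g,
    f_p = logistic_curve(stats::qlogis(f_p), 0),
    f_n = fecundity_model(log(f_n), 0),
    recruits = recruit_params(f_g, juv_mean, juv_sd),
    rho = rho)
}

# random right-censored survival table sharing entry day 60
random_survival_table <- function(n = 25, censor_frac = 0.3, end = 200) {
  exit <- 60L + sample.int(end - 60L, n, replace = TRUE)
  event <- ifelse(stats::runif(n) < censor_frac, "censored", "death")
  data.frame(fish_id = sprintf("f%03d", seq_len(n)), entry_day = 60L,
             exit_day = exit, event = event, stringsAsFactors = FALSE)
}
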