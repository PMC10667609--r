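make_small_fit_and_cohort <- function(seed = 31) {
  co <- simulate_experiment(default_config(), seed = seed)
  # two treatments (six tanks) keep the random-effect scales identifiable
  growth <- co$growth[co$growth$treatment %in% c("conti_20", "conti_30"), ]
  fit <- suppressWarnings(
    fit_growth(growth, test_mcmc_config(n_chains = 2, n_burnin = 1000,
                                        n_iterations = 1200, thin = 4,
                                        seed = seed)))
  list(fit = fit, cohort = co)
}

test_that("bootstrap bookkeeping, determinism and percentile oracle", {
  x <- make_small_fit_and_cohort(seed = 31)
  res <- bootstrap_demography(x$fit, x$cohort, n_boot = 60, seed = 4,
                              treatments = "conti_30", n_mesh = 100)
  r <- res$conti_30
  expect_identical(length(r$lambda), 60L)
  expect_identical(length(r$T), 60L)
  expect_identical(sum(is.na(r$lambda)), r$n_failed)
  # independent sort-based percentile routine (type-7 interpolation)
  manual_q <- function(x, p) {
    x <- sort(x[is.finite(x)])
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(r$ci_lambda,
               c(manual_q(r$lambda, 0.025), manual_q(r$lambda, 0.975)))
  expect_equal(r$ci_T, c(manual_q(r$T, 0.025), manual_q(r$T, 0.975)))
  expect_true(r$ci_lambda[1] <= r$median_lambda &&
                r$median_lambda <= r$ci_lambda[2])
  # reproducible under the same seed
  res2 <- bootstrap_demography(x$fit, x$cohort, n_boot = 60, seed = 4,
                               treatments = "conti_30", n_mesh = 100)
  expect_identical(res$conti_30$lambda, res2$conti_30$lambda)
})

test_that("degenerate posterior without resampling gives zero-width CIs", {
  x <- make_small_fit_and_cohort(seed = 32)
  fit <- x$fit
  fit$draws <- fit$draws[rep(1, 50), ]
  res <- bootstrap_demography(fit, x$cohort, n_boot = 20, seed = 1,
                              treatments = "conti_30", n_mesh = 80,
                              resample_data = FALSE)
  r <- res$conti_30
  expect_equal(diff(r$ci_lambda), 0)
  expect_equal(diff(r$ci_T), 0)
  expect_identical(r$n_failed, 0L)
})

test_that("CI-overlap comparison uses the closed-interval convention", {
  a <- fake_boot(ci_lambda = c(1.00, 1.01), ci_T = c(100, 120))
  expect_false(compare_by_ci(a, a, "lambda"))
  b <- fake_boot(ci_lambda = c(1.02, 1.03), ci_T = c(121, 130))
  expect_true(compare_by_ci(a, b, "lambda"))
  expect_true(compare_by_ci(b, a, "lambda"))
  touch <- fake_boot(ci_lambda = c(1.01, 1.02), ci_T = c(120, 125))
  expect_false(compare_by_ci(a, touch, "lambda"))
  expect_false(compare_by_ci(a, touch, "T"))
  expect_true(compare_by_ci(a, b, "T"))
})

test_that("finite-difference eigenvalue sensitivity matches the adjoint formula", {
  set.seed(71)
  for (i in 1:5) {
    n <- 12
    K <- matrix(stats::runif(n * n, 0.01, 0.2), n)
    est <- asymptotic_lambda(K, tol = 1e-13)
    adj <- outer(est$v, est$w) / sum(est$v * est$w)
    for (probe in 1:4) {
      ij <- sample.int(n, 2, replace = TRUE)
      d <- 1e-6
      Kp <- K; Kp[ij[1], ij[2]] <- K[ij[1], ij[2]] + d
      Km <- K; Km[ij[1], ij[2]] <- K[ij[1], ij[2]] - d
      fd <- (asymptotic_lambda(Kp, tol = 1e-13)$lambda -
               asymptotic_lambda(Km, tol = 1e-13)$lambda) / (2 * d)
      expect_equal(fd, adj[ij[1], ij[2]], tolerance = 1e-4)
    }
  }
})

test_that("vital-rate sensitivities have the expected structure", {
  grid <- build_grid(2.2, 3.6, 100)
  vit <- flat_vitals(s = 0.95, f_p = 0.6, f_n = 3, f_g = 0.02, rho = 0.5)
  # exclude the f_p shape parameters: a flat reproduction curve has no
  # defined midpoint
  pars <- c("s_intercept", "s_slope", "fec_a", "fec_b", "f_g", "rho",
            "juvenile_mean", "juvenile_sd", "sd_g", "l_inf", "k")
  rep_ <- sensitivity_analysis(vit, grid, delta = 0.01, parameters = pars)
  expect_s3_class(rep_, "sensitivity_report")
  expect_true(all(is.finite(rep_$d_lambda)))
  # more recruitment always helps
  expect_gt(rep_$d_lambda[rep_$parameter == "f_g"], 0)
  expect_gt(rep_$d_lambda[rep_$parameter == "rho"], 0)
  expect_gt(rep_$d_lambda[rep_$parameter == "fec_a"], 0)
  # scalar-limit check: lambda = s + fp*fn*fg*rho so dlambda/dfg = fp*fn*rho
  expect_equal(rep_$d_lambda[rep_$parameter == "f_g"], 0.6 * 3 * 0.5,
               tolerance = 1e-3)
  # dead parameter: with f_g = 0 the fertility kernel vanishes and rho
  # cannot matter
  vit0 <- flat_vitals(s = 0.95, f_p = 0.6, f_n = 3, f_g = 0, rho = 0.5)
  rep0 <- sensitivity_analysis(vit0, grid, delta = 0.01,
                               parameters = c("rho", "fec_a"))
  expect_equal(rep0$d_lambda, c(0, 0), tolerance = 1e-12)
  expect_error(sensitivity_analysis(vit, grid, delta = -0.1))
})

test_that("probability perturbations are clamped at one and flagged", {
  grid <- build_grid(2.2, 3.6, 60)
  vit <- flat_vitals(s = 0.9, f_p = 0.6, f_n = 1.5, f_g = 1.0, rho = 0.995)
  rep_ <- sensitivity_analysis(vit, grid, delta = 0.01,
                               parameters = c("f_g", "rho"))
  expect_true(all(rep_$clamped))
  expect_true(all(is.finite(rep_$d_lambda)))
})

test_that("bootstrap intervals cover the known synthetic growth rate", {
  cfg <- default_config()
  tr <- cfg$treatments["conti_30", ]
  p_true <- vb_params(tr$l_inf, tr$k, tr$t0)
  s_true <- logistic_curve(stats::qlogis(exp(-tr$hazard)), 0)
  fp_true <- reproduction_probability(log(tr$maturity_length), 50)
  fn_true <- fecundity_model(tr$fec_a, tr$fec_b)
  n_outer <- 20L
  covered <- 0L
  for (i in seq_len(n_outer)) {
    x <- make_small_fit_and_cohort(seed = 700 + i)
    res <- bootstrap_demography(x$fit, x$cohort, n_boot = 100,
                                seed = 700 + i, treatments = "conti_30",
                                n_mesh = 100)
    # estimand: lambda of the generating vital rates at the same
    # discretization the replicate used
    grid <- default_grid(
      posterior_point(x$fit, "conti_30"),
      x$cohort$growth[x$cohort$growth$treatment == "conti_30", ], 100)
    vit_true <- vital_rates(s_true, p_true, 0.03, fp_true, fn_true,
                            x$cohort$recruits, 0.5)
    lam_true <- treatment_demography(vit_true, grid)$lambda
    ci <- res$conti_30$ci_lambda
    if (ci[1] <= lam_true && lam_true <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, ceiling(0.85 * n_outer))
})
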