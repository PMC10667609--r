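test_that("vb_length matches the closed form", {
  p <- vb_params(30, 0.02, 0)
  expect_equal(vb_length(vb_params(25, 0.015, 12), 12), 0)
  expect_equal(vb_length(p, 1e6), 30, tolerance = 1e-9)
  expect_equal(vb_length(p, 100), 25.93994151, tolerance = 1e-7)
  expect_equal(age_to_size(p, 100), log(25.93994151), tolerance = 1e-7)
})

test_that("vb_step is the one-day advance of the growth curve", {
  p <- vb_params(30, 0.02, 0)
  expect_equal(vb_step(p, 30), 30)                      # fixed point
  expect_equal(vb_step(vb_params(30, 0, 5), 17.5), 17.5)  # K = 0
  expect_equal(vb_step(p, vb_length(p, 100)), vb_length(p, 101),
               tolerance = 1e-12)
  expect_equal(vb_step(p, 25.9399), 26.0202, tolerance = 1e-4)
})

test_that("one-day update identity holds over random parameters and ages", {
  set.seed(404)
  n <- 2000
  l_inf <- stats::runif(n, 5, 60)
  k <- stats::runif(n, 1e-4, 0.15)
  t0 <- stats::runif(n, -30, 30)
  t <- stats::runif(n, 0, 400)
  lt <- l_inf * (1 - exp(-k * (t - t0)))
  lt1_step <- lt * exp(-k) + l_inf * (1 - exp(-k))
  lt1_curve <- l_inf * (1 - exp(-k * (t + 1 - t0)))
  expect_lt(max(abs(lt1_step - lt1_curve)), 1e-10)
})

test_that("run_mcmc retains the scheduled draw count and samples a known target", {
  # standard bivariate normal: closed-form moments are the oracle
  lp <- function(th) -0.5 * sum(th^2)
  cfg <- mcmc_config(n_chains = 3, n_burnin = 500, n_iterations = 4000,
                     thin = 4, seed = 2)
  fit <- run_mcmc(lp, c(5, -5), cfg, par_names = c("x", "y"))
  expect_identical(nrow(fit$draws), 3L * 4000L %/% 4L)
  expect_identical(length(unique(fit$chain)), 3L)
  expect_lt(max(abs(colMeans(fit$draws))), 0.15)
  expect_equal(unname(apply(fit$draws, 2, stats::sd)), c(1, 1),
               tolerance = 0.1)
  expect_true(all(fit$rhat < 1.1))
})

test_that("run_mcmc agrees with the conjugate normal-mean posterior", {
  set.seed(8)
  y <- stats::rnorm(40, 3, 1.5)
  sigma <- 1.5; tau0 <- 10
  lp <- function(th) -sum((y - th)^2) / (2 * sigma^2) - th^2 / (2 * tau0^2)
  post_prec <- length(y) / sigma^2 + 1 / tau0^2
  exact_mean <- sum(y) / sigma^2 / post_prec
  exact_sd <- sqrt(1 / post_prec)
  fit <- run_mcmc(lp, 0, mcmc_config(n_chains = 2, n_burnin = 500,
                                     n_iterations = 8000, thin = 4, seed = 5))
  expect_equal(mean(fit$draws), exact_mean, tolerance = 3 * exact_sd / 30)
  expect_equal(stats::sd(fit$draws), exact_sd, tolerance = 0.15 * exact_sd)
})

test_that("fit_growth validates its inputs", {
  co <- simulate_experiment(default_config(), seed = 1)
  expect_error(fit_growth(co$growth[0, ]), "empty")
  one_tank <- co$growth[co$growth$tank_id == co$growth$tank_id[1], ]
  expect_error(fit_growth(one_tank), "2 tanks")
  two_tanks <- co$growth[co$growth$tank_id %in%
                           unique(co$growth$tank_id)[1:2], ]
  one_age <- two_tanks[two_tanks$age_days == 30, ]
  expect_error(fit_growth(one_age), "distinct ages")
})

test_that("posterior recovers the generating parameters on two treatments", {
  growth <- two_treatment_growth(seed = 21)
  fit <- suppressWarnings(fit_growth(growth, quick_mcmc(seed = 2)))
  cfg <- default_config()
  expect_identical(nrow(fit$draws), 2L * 1600L %/% 8L)
  for (trt in c("conti_20", "conti_30")) {
    d <- treatment_draws(fit, trt)
    tr <- cfg$treatments[trt, ]
    z <- abs(colMeans(d) - c(tr$l_inf, tr$k, tr$t0)) / apply(d, 2, stats::sd)
    expect_true(all(z < 4), info = trt)
  }
  # residual sd posterior should sit near the generating 0.9 mm
  expect_equal(mean(fit$draws[, "sigma"]), 0.9, tolerance = 0.2)
})

test_that("sampler agrees with JAGS on a single-curve model", {
  skip_if_not_installed("rjags")
  # one tank, non-hierarchical: priors and likelihood identical in both
  set.seed(31)
  age <- rep(c(30, 60, 100, 150, 200, 300, 350), each = 8)
  truth <- vb_params(28, 0.015, -5)
  len <- vb_length(truth, age) + stats::rnorm(length(age), 0, 0.8)
  lp <- function(th) {
    if (th[4] <= 0 || th[4] >= 10) return(-Inf)
    mu <- th[1] * (1 - exp(-th[2] * (age - th[3])))
    -length(len) * log(th[4]) - sum((len - mu)^2) / (2 * th[4]^2) -
      0.0005 * (th[1]^2 + th[2]^2 + th[3]^2)
  }
  blocks <- list(list(idx = 1:3, prop_sd = c(0.3, 0.002, 1)),
                 list(idx = 4, prop_sd = 0.05))
  mine <- run_mcmc(lp, c(25, 0.02, 0, 1),
                   mcmc_config(n_chains = 2, n_burnin = 2000,
                               n_iterations = 20000, thin = 10, seed = 4),
                   blocks = blocks)
  model <- "model {
    for (i in 1:N) {
      mu[i] <- Linf * (1 - exp(-K * (age[i] - t0)))
      len[i] ~ dnorm(mu[i], tau)
    }
    Linf ~ dnorm(0, 0.001); K ~ dnorm(0, 0.001); t0 ~ dnorm(0, 0.001)
    sigma ~ dunif(0, 10); tau <- 1 / (sigma * sigma)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(N = length(len), age = age, len = len),
                          inits = list(Linf = 25, K = 0.02, t0 = 0, sigma = 1,
                                       .RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 9),
                          n.chains = 1, quiet = TRUE)
  stats::update(jm, 2000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("Linf", "K", "t0", "sigma"), 20000,
                            progress.bar = "none")[[1]]
  mine_mean <- colMeans(mine$draws)
  jags_mean <- colMeans(js)[c("Linf", "K", "t0", "sigma")]
  jags_sd <- apply(js, 2, stats::sd)[c("Linf", "K", "t0", "sigma")]
  expect_true(all(abs(mine_mean - jags_mean) < 0.5 * jags_sd))
})

test_that("prior sampling reproduces the vague treatment-level prior", {
  growth <- two_treatment_growth(seed = 22)
  fit <- suppressWarnings(
    fit_growth(growth,
               test_mcmc_config(n_chains = 2, n_burnin = 2000,
                                n_iterations = 20000, thin = 10, seed = 6),
               sample_prior = TRUE))
  # Normal(0, precision 0.001) has sd sqrt(1000)
  sds <- apply(fit$draws[, paste0("l_inf[", fit$treatments, "]")], 2,
               stats::sd)
  expect_equal(unname(sds), rep(sqrt(1000), 2), tolerance = 0.2)
  means <- colMeans(fit$draws[, paste0("k[", fit$treatments, "]")])
  expect_lt(max(abs(means)), 0.2 * sqrt(1000))
})

test_that("credibility bands summarize the posterior curves", {
  set.seed(77)
  draws <- cbind(stats::rnorm(400, 30, 1), stats::rnorm(400, 0.02, 0.002),
                 stats::rnorm(400, 0, 1))
  fit <- fake_posterior(draws)
  ages <- c(30, 100, 250)
  b <- posterior_growth_bands(fit, ages)
  expect_true(all(b$lo <= b$mean & b$mean <= b$hi))
  # independent sort-based quantile oracle at one age
  curves <- draws[, 1] * (1 - exp(-draws[, 2] * (100 - draws[, 3])))
  srt <- sort(curves)
  expect_equal(b$lo[b$age == 100], unname(stats::quantile(srt, 0.025)))
  expect_equal(b$hi[b$age == 100], unname(stats::quantile(srt, 0.975)))
  expect_equal(b$mean[b$age == 100], mean(curves))
  # degenerate posterior: zero-width band equal to the point curve
  fit0 <- fake_posterior(matrix(rep(c(30, 0.02, 0), each = 50), ncol = 3))
  b0 <- posterior_growth_bands(fit0, ages)
  expect_equal(b0$lo, b0$hi)
  expect_equal(b0$mean, vb_length(vb_params(30, 0.02, 0), ages))
  expect_error(posterior_growth_bands(fit, numeric(0)), "non-empty")
})

test_that("curve comparison flags exactly the disjoint-CI ages", {
  ages <- 1:10
  a <- data.frame(age = ages, lo = 0, hi = 1)
  expect_identical(nrow(compare_growth_curves(a, a)), 0L)
  b <- data.frame(age = ages, lo = 2, hi = 3)
  out <- compare_growth_curves(a, b)
  expect_equal(out, data.frame(start = 1, end = 10))
  # touching bands still overlap (closed intervals)
  touch <- data.frame(age = ages, lo = 1, hi = 2)
  expect_identical(nrow(compare_growth_curves(a, touch)), 0L)
  # interior runs are merged into intervals
  c_ <- data.frame(age = ages, lo = c(2, 2, 0, 0, 2, 2, 2, 0, 0, 0),
                   hi = c(3, 3, 1, 1, 3, 3, 3, 1, 1, 1))
  out2 <- compare_growth_curves(a, c_)
  expect_equal(out2, data.frame(start = c(1, 5), end = c(2, 7)))
  expect_error(compare_growth_curves(a, b[1:5, ]), "identical")
})
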