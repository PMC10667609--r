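test_that("product-limit estimate matches hand-computed values", {
  rec <- data.frame(entry_day = 60,
                    exit_day = c(61, 63, 100, 100, 100),
                    event = c("death", "death", rep("censored", 3)))
  km <- kaplan_meier(rec)
  expect_equal(km$time, c(61, 63))
  expect_equal(km$surv, c(4 / 5, (4 / 5) * (3 / 4)))
  expect_equal(km$n_risk, c(5L, 4L))
  # no deaths at all
  none <- data.frame(entry_day = 60, exit_day = 350, event = "censored")
  expect_identical(length(kaplan_meier(none)$time), 0L)
  expect_true(all(kaplan_meier(none)$daily$surv == 1))
  bad <- data.frame(entry_day = 60, exit_day = 59, event = "death")
  expect_error(kaplan_meier(bad), "exit before entry")
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(12)
  for (i in 1:50) {
    tab <- random_survival_table(n = sample(5:40, 1), censor_frac = 0)
    km <- kaplan_meier(tab)
    for (t in km$daily$day) {
      expect_equal(km$daily$surv[km$daily$day == t],
                   mean(tab$exit_day > t))
    }
  }
})

test_that("KM agrees with survival::survfit under censoring", {
  set.seed(13)
  for (i in 1:20) {
    tab <- random_survival_table(n = 40, censor_frac = 0.35)
    km <- kaplan_meier(tab)
    sf <- survival::survfit(
      survival::Surv(tab$exit_day - 60, tab$event == "death") ~ 1)
    sm <- summary(sf, times = km$time - 60)
    expect_equal(km$surv, sm$surv, tolerance = 1e-12)
  }
})

test_that("age_to_size composes the growth curve with the log map", {
  p <- vb_params(30, 0.02, 0)
  expect_equal(age_to_size(p, 100), log(25.9399), tolerance = 1e-4)
  expect_error(age_to_size(p, 0), "non-positive")
  ages <- seq(10, 350, by = 10)
  expect_true(all(diff(age_to_size(p, ages)) > 0))
})

test_that("size-independent mortality yields a flat fitted survival curve", {
  set.seed(14)
  p <- vb_params(30, 0.02, 0)
  # 400 fish with constant daily survival 0.99 from day 60
  n <- 400
  life <- stats::rgeom(n, 0.01) + 1
  exit <- pmin(60 + life, 350)
  tab <- data.frame(entry_day = 60, exit_day = exit,
                    event = ifelse(60 + life <= 350, "death", "censored"))
  s <- fit_survival_logistic(kaplan_meier(tab), p)
  z <- age_to_size(p, c(70, 150, 300))
  expect_equal(unname(predict_prob(s, z)), rep(0.99, 3), tolerance = 0.01)
})

test_that("per-step survival fit recovers known logistic coefficients", {
  p <- vb_params(30, 0.02, 0)
  n_cover <- 0L
  n_seeds <- 50L
  for (sd_i in seq_len(n_seeds)) {
    set.seed(500 + sd_i)
    n <- 300
    alive <- rep(TRUE, n)
    exit <- rep(350L, n)
    for (d in 61:350) {
      z <- age_to_size(p, d)
      pr <- stats::plogis(10 - 2 * z)    # daily survival at size z
      dies <- alive & (stats::runif(n) > pr)
      exit[dies] <- d
      alive <- alive & !dies
    }
    tab <- data.frame(entry_day = 60L, exit_day = exit,
                      event = ifelse(alive, "censored", "death"))
    d_tab <- kaplan_meier(tab)$daily
    zd <- age_to_size(p, d_tab$day)
    fit <- suppressWarnings(stats::glm(
      cbind(d_tab$n_risk - d_tab$n_event, d_tab$n_event) ~ zd,
      family = stats::binomial()))
    cf <- stats::coef(summary(fit))
    ci <- cf[2, 1] + c(-1.96, 1.96) * cf[2, 2]
    if (ci[1] <= -2 && -2 <= ci[2]) n_cover <- n_cover + 1L
    # the packaged fit must agree with the direct GLM route
    s <- fit_survival_logistic(kaplan_meier(tab), p)
    expect_equal(s$slope, unname(cf[2, 1]), tolerance = 1e-8)
  }
  expect_gte(n_cover, 0.9 * n_seeds)
})

test_that("reproduction probability is a smooth step at maturity", {
  z_mat <- log(16.8)
  fp <- reproduction_probability(z_mat, steepness = 50)
  expect_equal(predict_prob(fp, z_mat), 0.5)
  expect_gt(predict_prob(fp, z_mat + 0.3), 0.999)
  expect_lt(predict_prob(fp, z_mat - 0.3), 0.001)
  z <- seq(2, 4, length.out = 50)
  expect_true(all(diff(predict_prob(fp, z)) >= 0))
  expect_error(reproduction_probability(z_mat, steepness = -1))
})

test_that("Poisson fecundity fit recovers known coefficients", {
  n_cover <- 0L
  n_seeds <- 50L
  for (sd_i in seq_len(n_seeds)) {
    set.seed(900 + sd_i)
    len <- stats::runif(150, 12, 35)
    eggs <- stats::rpois(150, exp(0 + 1.2 * log(len)))
    clutch <- data.frame(female_length_mm = len, egg_count = eggs)
    f <- fit_fecundity(clutch)
    fit <- stats::glm(eggs ~ log(len), family = stats::poisson())
    cf <- stats::coef(summary(fit))
    expect_equal(f$b, unname(cf[2, 1]))
    ci <- cf[2, 1] + c(-1.96, 1.96) * cf[2, 2]
    if (ci[1] <= 1.2 && 1.2 <= ci[2]) n_cover <- n_cover + 1L
  }
  expect_gte(n_cover, 0.9 * n_seeds)
})

test_that("fecundity fit handles degenerate inputs", {
  clutch <- data.frame(female_length_mm = c(15, 20, 25, 30),
                       egg_count = c(7L, 7L, 7L, 7L))
  f <- fit_fecundity(clutch)
  expect_equal(f$b, 0, tolerance = 1e-6)
  expect_equal(exp(f$a), 7, tolerance = 1e-6)
  expect_error(fit_fecundity(clutch[1, ]), "2 distinct sizes")
  zero <- data.frame(female_length_mm = c(15, 25), egg_count = c(0L, 0L))
  expect_error(fit_fecundity(zero), "zero")
})

test_that("growth residual sd averages the per-age posterior spread", {
  # degenerate posterior: zero spread
  fit0 <- fake_posterior(matrix(rep(c(30, 0.02, 0), each = 20), ncol = 3))
  expect_equal(growth_residual_sd(fit0, "conti_20"), 0)
  # two-draw posterior: hand-computed oracle
  draws <- rbind(c(30, 0.02, 0), c(28, 0.025, 2))
  fit2 <- fake_posterior(draws)
  ages <- c(100, 200)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  hand <- mean(vapply(ages, function(a) {
    lt <- draws[, 1] * (1 - exp(-draws[, 2] * (a - draws[, 3])))
    lt1 <- lt * exp(-draws[, 2]) + draws[, 1] * (1 - exp(-draws[, 2]))
    psd(log(lt1))
  }, 0))
  expect_equal(growth_residual_sd(fit2, "conti_20", ages = ages), hand)
  # invariant under duplicating every draw
  fit4 <- fake_posterior(draws[c(1, 2, 1, 2), ])
  expect_equal(growth_residual_sd(fit4, "conti_20", ages = ages), hand)
  # mm-scale option
  hand_mm <- mean(vapply(ages, function(a) {
    lt <- draws[, 1] * (1 - exp(-draws[, 2] * (a - draws[, 3])))
    psd(lt * exp(-draws[, 2]) + draws[, 1] * (1 - exp(-draws[, 2])))
  }, 0))
  expect_equal(growth_residual_sd(fit2, "conti_20", ages = ages,
                                  scale = "mm"), hand_mm)
})

test_that("vital-rate probabilities stay within [0, 1]", {
  z <- seq(1.5, 4, length.out = 100)
  s <- logistic_curve(3, -0.5)
  fp <- reproduction_probability(log(20), 50)
  expect_true(all(predict_prob(s, z) > 0 & predict_prob(s, z) < 1))
  # the steep maturity step saturates in floating point but never leaves [0, 1]
  expect_true(all(predict_prob(fp, z) >= 0 & predict_prob(fp, z) <= 1))
  near <- log(20) + c(-0.05, 0.05)
  expect_true(all(predict_prob(fp, near) > 0 & predict_prob(fp, near) < 1))
  fn <- fecundity_model(-4.5, 2)
  expect_true(all(predict_eggs(fn, z) > 0))
})
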