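# closed-form inverse and log-determinant of a 3x3 correlation matrix;
# returns NULL when the matrix is not positive definite
corr3_inverse <- function(r1, r2, r3) {
  det <- 1 + 2 * r1 * r2 * r3 - r1^2 - r2^2 - r3^2
  if (det <= 0 || abs(r1) >= 1 || abs(r2) >= 1 || abs(r3) >= 1) return(NULL)
  adj <- matrix(c(1 - r3^2, r2 * r3 - r1, r1 * r3 - r2,
                  r2 * r3 - r1, 1 - r2^2, r1 * r2 - r3,
                  r1 * r3 - r2, r1 * r2 - r3, 1 - r1^2), 3, 3)
  list(inv = adj / det, logdet = log(det))
}

#' Fit the hierarchical Bayesian Von Bertalanffy growth model
#'
#' Samples the posterior of the hierarchical growth model: treatment-level
#' parameters (L_inf, K, t0 per temperature-by-feeding combination) with
#' vague Normal(0, precision `prior_precision`) priors; tank-level
#' deviations for the three parameters jointly multivariate-normal with
#' covariance assembled from three standard deviations (Uniform(0,
#' `ranef_sd_upper`) priors) and three correlations (Uniform(-1, 1)
#' priors, jointly truncated to the positive-definite region); observed
#' lengths Normal around the tank-level curve with residual sd sigma ~
#' Uniform(0, `sigma_upper`).
#'
#' Sampling uses the package's adaptive blockwise Metropolis sampler
#' ([run_mcmc()]): one block per treatment (the three hyper-parameters
#' jointly), one per tank (its deviation vector), univariate blocks for
#' the covariance components and sigma, plus likelihood-invariant
#' translation moves that shift a treatment's hyper-parameters against its
#' tanks' deviations to decorrelate the hierarchy. Split-R-hat is reported
#' per parameter; non-convergence (any R-hat > 1.1) sets `converged =
#' FALSE` with a warning, it is not an error.
#'
#' @param growth Growth table with columns `tank_id`, `treatment`,
#'   `age_days`, `length_mm` (as produced by [simulate_experiment()] or
#'   [read_cohort()]).
#' @param config An [mcmc_config()]; the paper-scale default retains
#'   10,000 draws, [test_mcmc_config()] is the desk-scale schedule.
#' @param sample_prior If `TRUE`, drop the likelihood and sample the prior
#'   (prior-predictive checking).
#' @return An object of class `vb_posterior`: retained draws (columns
#'   `l_inf[trt]`, `k[trt]`, `t0[trt]` per treatment, `sd_l_inf`, `sd_k`,
#'   `sd_t0`, `r1`, `r2`, `r3`, `sigma`, and `eps_*[tank]` per tank),
#'   chain index, R-hat values, the treatments and tanks fitted, and the
#'   schedule.
#' @export
fit_growth <- function(growth, config = test_mcmc_config(),
                       sample_prior = FALSE) {
  if (is.null(growth) || nrow(growth) == 0) {
    stop("growth table is empty", call. = FALSE)
  }
  stopifnot(all(c("tank_id", "treatment", "age_days", "length_mm")
                %in% names(growth)))
  keys <- intersect(treatment_keys(), unique(growth$treatment))
  if (length(keys) == 0) stop("no recognized treatments", call. = FALSE)
  tanks <- unique(growth[, c("tank_id", "treatment")])
  tanks <- tanks[order(match(tanks$treatment, keys), tanks$tank_id), ]
  if (nrow(tanks) < 2) {
    stop("at least 2 tanks are required to identify the tank random effect",
         call. = FALSE)
  }
  if (length(unique(growth$age_days)) < 2) {
    stop("at least 2 distinct ages are required", call. = FALSE)
  }

  n_trt <- length(keys)
  n_tank <- nrow(tanks)
  trt_of_tank <- match(tanks$treatment, keys)
  obs_tank <- match(growth$tank_id, tanks$tank_id)
  age <- as.numeric(growth$age_days)
  len <- as.numeric(growth$length_mm)
  n_obs <- length(len)

  # parameter vector layout
  i_ct <- seq_len(3 * n_trt)                      # l_inf,k,t0 per treatment
  base <- 3 * n_trt
  i_sd <- base + 1:3
  i_r <- base + 4:6
  i_sig <- base + 7L
  i_eps <- base + 7L + seq_len(3 * n_tank)
  npar <- base + 7L + 3L * n_tank
  par_names <- c(
    as.vector(t(outer(keys, c("l_inf", "k", "t0"),
                      function(k, p) paste0(p, "[", k, "]")))),
    "sd_l_inf", "sd_k", "sd_t0", "r1", "r2", "r3", "sigma",
    as.vector(t(outer(tanks$tank_id, c("eps_l_inf", "eps_k", "eps_t0"),
                      function(k, p) paste0(p, "[", k, "]")))))

  prec <- config$prior_precision
  sd_up <- config$ranef_sd_upper
  sig_up <- config$sigma_upper
  use_lik <- !sample_prior
  log2pi <- log(2 * pi)

  log_post <- function(theta) {
    sds <- theta[i_sd]
    if (any(sds <= 0) || any(sds >= sd_up)) return(-Inf)
    rs <- theta[i_r]
    sig <- theta[i_sig]
    if (sig <= 0 || sig >= sig_up) return(-Inf)
    ri <- corr3_inverse(rs[1], rs[2], rs[3])
    if (is.null(ri)) return(-Inf)

    ct <- matrix(theta[i_ct], nrow = 3)            # 3 x n_trt
    eps <- matrix(theta[i_eps], nrow = 3)          # 3 x n_tank
    # tank random-effect prior: MVN(0, D R D)
    e_std <- eps / sds
    quad <- sum(e_std * (ri$inv %*% e_std))
    lp <- -0.5 * n_tank * (3 * log2pi + 2 * sum(log(sds)) + ri$logdet) -
      0.5 * quad
    # vague normal hyper-priors
    lp <- lp - 0.5 * prec * sum(ct^2)
    if (use_lik) {
      ptank <- ct[, trt_of_tank] + eps              # 3 x n_tank
      l_inf_o <- ptank[1, obs_tank]
      k_o <- ptank[2, obs_tank]
      t0_o <- ptank[3, obs_tank]
      mu <- l_inf_o * (1 - exp(-k_o * (age - t0_o)))
      lp <- lp - n_obs * log(sig) - 0.5 * n_obs * log2pi -
        sum((len - mu)^2) / (2 * sig^2)
    }
    lp
  }

  # blocks: per-treatment hypers, per-tank deviations, covariance
  # components, sigma, and translation moves along the hierarchy
  vb_ps <- c(0.3, 0.0015, 0.8)   # typical posterior scales of (L_inf, K, t0)
  blocks <- list()
  for (g in seq_len(n_trt)) {
    blocks[[length(blocks) + 1L]] <- list(idx = (3 * (g - 1) + 1):(3 * g),
                                          scale = 1, prop_sd = vb_ps)
  }
  for (t in seq_len(n_tank)) {
    blocks[[length(blocks) + 1L]] <-
      list(idx = base + 7L + (3 * (t - 1) + 1):(3 * t),
           scale = 1, prop_sd = vb_ps)
  }
  comp_ps <- c(0.2, 0.0005, 0.5)
  for (m in seq_along(i_sd)) {
    blocks[[length(blocks) + 1L]] <- list(idx = i_sd[m],
                                          scale = 1, prop_sd = comp_ps[m])
  }
  # the three correlations are weakly identified and posterior-correlated
  # through the PD constraint; update them jointly
  blocks[[length(blocks) + 1L]] <- list(idx = i_r, scale = 1,
                                        prop_sd = rep(0.2, 3))
  blocks[[length(blocks) + 1L]] <- list(idx = i_sig, scale = 1,
                                        prop_sd = 0.05)
  for (g in seq_len(n_trt)) {
    idx_ct <- (3 * (g - 1) + 1):(3 * g)
    idx_e <- i_eps[rep(3 * (which(trt_of_tank == g) - 1), each = 3) + 1:3]
    eps_mat_idx <- matrix(idx_e, nrow = 3)
    local({
      ic <- idx_ct; ie <- eps_mat_idx
      blocks[[length(blocks) + 1L]] <<- list(
        d = 3L, scale = 1, prop_sd = vb_ps,
        move = function(theta, step) {
          theta[ic] <- theta[ic] + step
          theta[ie] <- theta[ie] - step   # recycles column-wise over tanks
          theta
        })
    })
  }

  # crude per-treatment least-squares start, jittered per chain
  start_trt <- t(vapply(keys, function(kk) {
    g <- growth[growth$treatment == kk, ]
    l0 <- max(g$length_mm) * 1.05
    fn <- function(p) {
      mu <- p[1] * (1 - exp(-exp(p[2]) * (g$age_days - p[3])))
      sum((g$length_mm - mu)^2)
    }
    o <- stats::optim(c(l0, log(2 / max(g$age_days)), 0), fn)
    c(o$par[1], exp(o$par[2]), o$par[3])
  }, numeric(3)))
  resid_sd <- 1
  if (use_lik) {
    mu0 <- vapply(seq_len(n_obs), function(i) {
      p <- start_trt[match(growth$treatment[i], keys), ]
      p[1] * (1 - exp(-p[2] * (age[i] - p[3])))
    }, 0)
    resid_sd <- min(max(stats::sd(len - mu0), 0.05), sig_up * 0.9)
  }

  init_fun <- function(chain) {
    jit <- 1 + 0.05 * (chain - (config$n_chains + 1) / 2) / config$n_chains
    theta <- numeric(npar)
    theta[i_ct] <- as.vector(t(start_trt)) * jit
    theta[i_sd] <- c(0.5, 0.005, 1) * jit
    theta[i_r] <- 0
    theta[i_sig] <- resid_sd * jit
    theta[i_eps] <- 0
    theta
  }

  fit <- run_mcmc(log_post, init_fun, config, blocks, par_names = par_names)
  if (!isTRUE(fit$converged)) {
    warning("MCMC convergence diagnostics exceed 1.1 for some parameters; ",
            "treat estimates with caution", call. = FALSE)
  }
  k_cols <- paste0("k[", keys, "]")
  bad_k <- vapply(k_cols, function(cc) mean(fit$draws[, cc] <= 0), 0)
  if (use_lik && any(bad_k > 0.01)) {
    warning("more than 1% posterior mass on K <= 0 for: ",
            paste(keys[bad_k > 0.01], collapse = ", "), call. = FALSE)
  }
  structure(list(draws = fit$draws, chain = fit$chain, rhat = fit$rhat,
                 accept = fit$accept, converged = fit$converged,
                 treatments = keys, tanks = tanks, config = config,
                 sample_prior = sample_prior),
            class = "vb_posterior")
}

#' @export
print.vb_posterior <- function(x, ...) {
  cat(sprintf("Hierarchical Von Bertalanffy posterior: %d draws, %d chains\n",
              nrow(x$draws), x$config$n_chains))
  cat("  treatments:", paste(x$treatments, collapse = ", "), "\n")
  cat(sprintf("  max split-Rhat: %.3f (converged: %s)\n",
              max(x$rhat, na.rm = TRUE), x$converged))
  invisible(x)
}

#' Extract treatment-level posterior draws
#'
#' @param fit A `vb_posterior` from [fit_growth()].
#' @param treatment Treatment key.
#' @return Matrix of retained draws with columns `l_inf`, `k`, `t0`.
#' @export
treatment_draws <- function(fit, treatment) {
  stopifnot(inherits(fit, "vb_posterior"), treatment %in% fit$treatments)
  m <- fit$draws[, paste0(c("l_inf", "k", "t0"), "[", treatment, "]"),
                 drop = FALSE]
  colnames(m) <- c("l_inf", "k", "t0")
  m
}

#' Posterior-mean growth parameters for one treatment
#'
#' @inheritParams treatment_draws
#' @return A [vb_params()] object of posterior means.
#' @export
posterior_point <- function(fit, treatment) {
  m <- colMeans(treatment_draws(fit, treatment))
  vb_params(m[["l_inf"]], m[["k"]], m[["t0"]])
}

#' Posterior growth curves with credibility bands
#'
#' Evaluates the Von Bertalanffy curve at each retained treatment-level
#' draw and set of ages, and summarizes pointwise with the posterior mean
#' and the 2.5%/97.5% quantiles.
#'
#' @param fit A `vb_posterior`.
#' @param ages Ages (days) at which to evaluate the curves.
#' @param treatments Treatment keys (default: all fitted).
#' @return A data.frame of class `growth_band` with columns `treatment`,
#'   `age`, `mean`, `lo`, `hi`.
#' @export
posterior_growth_bands <- function(fit, ages, treatments = fit$treatments) {
  stopifnot(inherits(fit, "vb_posterior"))
  if (length(ages) == 0) stop("ages must be non-empty", call. = FALSE)
  if (nrow(fit$draws) == 0) stop("posterior is empty", call. = FALSE)
  out <- lapply(treatments, function(kk) {
    d <- treatment_draws(fit, kk)
    curves <- vapply(ages, function(a) {
      d[, "l_inf"] * (1 - exp(-d[, "k"] * (a - d[, "t0"])))
    }, numeric(nrow(d)))
    curves <- matrix(curves, nrow = nrow(d))
    data.frame(treatment = kk, age = ages,
               mean = unname(colMeans(curves)),
               lo = unname(apply(curves, 2, stats::quantile, 0.025)),
               hi = unname(apply(curves, 2, stats::quantile, 0.975)),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("growth_band", "data.frame"))
}

#' Age intervals where two credibility bands do not overlap
#'
#' Flags an age as significantly different when the two closed credibility
#' intervals are disjoint (bands merely touching at an endpoint still
#' overlap, hence are not flagged), and merges contiguous flagged ages
#' into intervals.
#'
#' @param a,b `growth_band` rows for one treatment each, on identical age
#'   vectors.
#' @return A data.frame with columns `start`, `end` (ages bounding each
#'   non-overlap interval); zero rows when the bands always overlap.
#' @export
compare_growth_curves <- function(a, b) {
  if (!identical(as.numeric(a$age), as.numeric(b$age))) {
    stop("age vectors must be identical", call. = FALSE)
  }
  disjoint <- (a$lo > b$hi) | (b$lo > a$hi)
  if (!any(disjoint)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  r <- rle(disjoint)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = a$age[starts[keep]], end = a$age[ends[keep]])
}
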