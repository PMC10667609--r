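#' MCMC schedule configuration
#'
#' Holds the sampling schedule and prior constants of the hierarchical
#' growth model. The default schedule (5 chains, 50,000 burn-in, 400,000
#' post-burn-in iterations, one retained draw every 200) retains exactly
#' 10,000 posterior draws per quantity. [test_mcmc_config()] provides the
#' desk-scale schedule used throughout the test suite.
#'
#' @param n_chains Number of independent chains.
#' @param n_burnin Burn-in (adaptation) iterations per chain, discarded.
#' @param n_iterations Post-burn-in iterations per chain.
#' @param thin Keep one draw every `thin` iterations; must divide
#'   `n_iterations`.
#' @param prior_precision Precision (1/variance) of the Normal(0, .) priors
#'   on the treatment-level growth parameters.
#' @param sigma_upper Upper bound of the Uniform(0, .) prior on the
#'   residual length sd.
#' @param ranef_sd_upper Upper bound of the Uniform(0, .) priors on the
#'   random-effect standard deviations.
#' @param seed Integer seed; chain c uses stream `seed + c`.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 5, n_burnin = 50000, n_iterations = 400000,
                        thin = 200, prior_precision = 0.001,
                        sigma_upper = 10, ranef_sd_upper = 10, seed = 1) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_iterations >= 1, thin >= 1)
  if (n_iterations %% thin != 0) {
    stop("thin must divide n_iterations evenly", call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_iterations = as.integer(n_iterations),
                 thin = as.integer(thin),
                 prior_precision = prior_precision,
                 sigma_upper = sigma_upper,
                 ranef_sd_upper = ranef_sd_upper,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param ... Overrides passed to [mcmc_config()].
#' @export
test_mcmc_config <- function(...) {
  defaults <- list(n_chains = 4, n_burnin = 2000, n_iterations = 5000,
                   thin = 10, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(mcmc_config, args)
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, per parameter. Values near 1 indicate between-chain agreement;
#' the fitter flags any parameter above 1.1.
#'
#' @param draws Matrix of retained draws (rows) by parameters (columns).
#' @param chain Integer chain index per row.
#' @return Named numeric vector of R-hat values (NA for zero-variance
#'   parameters).
#' @export
split_rhat <- function(draws, chain) {
  draws <- as.matrix(draws)
  stopifnot(nrow(draws) == length(chain))
  chains <- split(seq_len(nrow(draws)), chain)
  halves <- list()
  for (idx in chains) {
    n <- length(idx)
    if (n < 4) next
    h <- n %/% 2
    halves[[length(halves) + 1L]] <- idx[seq_len(h)]
    halves[[length(halves) + 1L]] <- idx[(n - h + 1):n]
  }
  if (length(halves) < 2) {
    return(stats::setNames(rep(NA_real_, ncol(draws)), colnames(draws)))
  }
  apply(draws, 2, function(x) {
    means <- vapply(halves, function(i) mean(x[i]), 0)
    vars <- vapply(halves, function(i) stats::var(x[i]), 0)
    n <- length(halves[[1]])
    w <- mean(vars)
    b <- n * stats::var(means)
    if (!is.finite(w) || w <= 0) return(NA_real_)
    sqrt(((n - 1) / n * w + b / n) / w)
  })
}

# One adaptive blockwise random-walk Metropolis sampler drives every
# Bayesian fit in the package. `log_post` is an arbitrary log target;
# blocks are updated in turn with multivariate normal proposals whose
# scale (and, for multivariate blocks, covariance) adapts during burn-in
# via Robbins-Monro, then freezes. A block may instead carry a custom
# symmetric `move(theta, step)`; the hierarchical growth model uses this
# for likelihood-invariant translation moves between hyper-parameters and
# their random effects.

#' Run adaptive blockwise Metropolis MCMC
#'
#' Generic random-walk Metropolis sampler over an arbitrary log posterior.
#' Proposal scales (and proposal covariances for multivariate blocks)
#' adapt towards standard acceptance targets (0.44 univariate, 0.234
#' multivariate) during burn-in and are frozen afterwards, so the retained
#' chain is a valid Markov chain. Exactly
#' `n_chains * n_iterations / thin` draws are retained.
#'
#' @param log_post Function `theta -> log posterior density` (unnormalized;
#'   `-Inf` outside the support).
#' @param init Numeric start vector, or a function `chain -> vector` for
#'   overdispersed starts.
#' @param config An [mcmc_config()] (only the schedule and seed fields are
#'   used here).
#' @param blocks List of blocks; each is a list with either `idx` (integer
#'   positions updated jointly by a random-walk proposal) or `move`
#'   (a function `(theta, step)` returning a proposal, with `step` a
#'   standard-normal vector scaled by the adapted block scale). Optional
#'   fields: `scale` (initial global step scale), `prop_sd`
#'   (per-component proposal sds, for blocks mixing parameters of very
#'   different magnitudes), `d` (dimension of a custom move). Default:
#'   a single block over all parameters.
#' @param par_names Optional column names for the draws.
#' @return A list of class `mcmc_fit` with elements `draws` (matrix),
#'   `chain`, `rhat`, `accept` (per block), `config` and `converged`
#'   (all R-hat <= 1.1, `NA`-tolerant).
#' @examples
#' lp <- function(th) -0.5 * sum(th^2)
#' fit <- run_mcmc(lp, c(0, 0), test_mcmc_config(n_chains = 2,
#'   n_burnin = 200, n_iterations = 1000, thin = 5))
#' nrow(fit$draws)  # 2 * 1000 / 5
#' @export
run_mcmc <- function(log_post, init, config = test_mcmc_config(),
                     blocks = NULL, par_names = NULL) {
  init_fun <- if (is.function(init)) init else function(chain) init
  theta0 <- init_fun(1L)
  npar <- length(theta0)
  if (is.null(blocks)) blocks <- list(list(idx = seq_len(npar)))
  nb <- length(blocks)

  n_keep_chain <- config$n_iterations %/% config$thin
  total_keep <- config$n_chains * n_keep_chain
  draws <- matrix(NA_real_, total_keep, npar)
  chain_id <- integer(total_keep)
  accept <- matrix(0, config$n_chains, nb)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    theta <- init_fun(ch)
    stopifnot(length(theta) == npar)
    lp <- log_post(theta)
    if (!is.finite(lp)) {
      stop("initial value has non-finite log posterior", call. = FALSE)
    }

    # per-block adaptation state
    b_idx <- lapply(blocks, function(b) b$idx)
    b_move <- lapply(blocks, function(b) b$move)
    b_d <- vapply(seq_len(nb), function(j) {
      if (is.null(b_move[[j]])) length(b_idx[[j]]) else
        if (is.null(blocks[[j]]$d)) 1L else as.integer(blocks[[j]]$d)
    }, 0L)
    b_target <- ifelse(b_d == 1L, 0.44, 0.234)
    b_ls <- vapply(seq_len(nb), function(j) {
      if (!is.null(blocks[[j]]$scale)) log(blocks[[j]]$scale) else log(0.1)
    }, 0)
    b_ps <- lapply(seq_len(nb), function(j) {
      if (!is.null(blocks[[j]]$prop_sd)) blocks[[j]]$prop_sd else
        rep(1, b_d[j])
    })
    b_chol <- vector("list", nb)          # adapted proposal shape
    b_mean <- lapply(b_d, function(d) numeric(d))
    b_m2 <- lapply(b_d, function(d) matrix(0, d, d))
    b_n <- numeric(nb)
    n_acc <- numeric(nb)
    n_try <- numeric(nb)

    total_iter <- config$n_burnin + config$n_iterations
    keep_row <- (ch - 1L) * n_keep_chain

    for (it in seq_len(total_iter)) {
      adapting <- it <= config$n_burnin
      for (j in seq_len(nb)) {
        step <- stats::rnorm(b_d[j])
        if (is.null(b_move[[j]])) {
          idx <- b_idx[[j]]
          step <- if (!is.null(b_chol[[j]])) drop(b_chol[[j]] %*% step)
                  else step * b_ps[[j]]
          prop <- theta
          prop[idx] <- theta[idx] + exp(b_ls[j]) * step
        } else {
          prop <- b_move[[j]](theta, exp(b_ls[j]) * step * b_ps[[j]])
        }
        lp_prop <- log_post(prop)
        acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp
        if (acc) { theta <- prop; lp <- lp_prop }
        n_try[j] <- n_try[j] + 1
        if (acc) n_acc[j] <- n_acc[j] + 1
        if (adapting) {
          gamma <- min(0.5, 2 / sqrt(it))
          b_ls[j] <- b_ls[j] + gamma * ((if (acc) 1 else 0) - b_target[j])
          if (is.null(b_move[[j]]) && b_d[j] > 1L) {
            # running covariance of the block for shaped proposals
            x <- theta[b_idx[[j]]]
            b_n[j] <- b_n[j] + 1
            delta <- x - b_mean[[j]]
            b_mean[[j]] <- b_mean[[j]] + delta / b_n[j]
            b_m2[[j]] <- b_m2[[j]] + tcrossprod(delta, x - b_mean[[j]])
            if (b_n[j] >= 200 && b_n[j] %% 100 == 0) {
              cv <- b_m2[[j]] / (b_n[j] - 1)
              cv <- cv + diag(1e-10 + 1e-6 * diag(cv), b_d[j])
              ch_try <- tryCatch(chol(cv), error = function(e) NULL)
              if (!is.null(ch_try)) {
                # keep the overall step magnitude continuous with the
                # initial per-component proposal sds; exp(ls) re-adapts
                b_chol[[j]] <- t(ch_try) *
                  exp(mean(log(b_ps[[j]])) - mean(log(sqrt(diag(cv)))))
              }
            }
          }
        }
      }
      if (it > config$n_burnin) {
        k <- it - config$n_burnin
        if (k %% config$thin == 0) {
          keep_row <- keep_row + 1L
          draws[keep_row, ] <- theta
          chain_id[keep_row] <- ch
        }
      }
    }
    accept[ch, ] <- n_acc / n_try
  }

  if (!is.null(par_names)) colnames(draws) <- par_names
  rhat <- split_rhat(draws, chain_id)
  conv <- all(rhat[!is.na(rhat)] <= 1.1)
  structure(list(draws = draws, chain = chain_id, rhat = rhat,
                 accept = accept, config = config, converged = conv),
            class = "mcmc_fit")
}
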