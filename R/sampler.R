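#' MCMC configuration
#'
#' Chain settings for [run_chains()]. Defaults are desk-scale: M = 150
#' augmented individuals, three chains of 5,000 iterations with 1,000
#' burn-in after a 1,000-iteration adaptive phase, no thinning. Full-scale
#' survey fits (M = 500, 50,000 iterations, 10,000 burn-in) are obtained by
#' setting those fields explicitly.
#'
#' @param n_chains number of independent chains (>= 1).
#' @param n_iter post-adaptation iterations per chain.
#' @param n_burnin burn-in iterations discarded from `n_iter`.
#' @param n_adapt adaptive-phase iterations (proposal scales are tuned
#'   toward acceptance rates in 0.2-0.45, then frozen).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param M data-augmentation size; the hard upper bound on abundance N.
#' @param seed integer; per-chain seeds default to `seed + 0:(n_chains-1)`.
#' @param seeds explicit per-chain seeds (overrides `seed`); must be distinct.
#' @param steps initial proposal scales: `s` (metres), `log_lambda0`,
#'   `log_sigma` (log-scale sds).
#' @param snapshot_every retain a (z, s) snapshot every this many retained
#'   iterations, for density surfaces.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 5000, n_burnin = 1000,
                        n_adapt = 1000, thin = 1, M = 150,
                        seed = 1, seeds = NULL,
                        steps = c(s = 100, log_lambda0 = 0.4, log_sigma = 0.15),
                        snapshot_every = 10) {
  if (is.null(seeds)) seeds <- as.integer(seed) + seq_len(n_chains) - 1L
  if (length(seeds) != n_chains || anyDuplicated(seeds)) {
    stop_invalid("seeds must be one distinct integer per chain")
  }
  if (n_burnin >= n_iter) stop_invalid("n_burnin must be < n_iter")
  if (thin < 1) stop_invalid("thin must be >= 1")
  if (M < 1) stop_invalid("M must be >= 1")
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         n_burnin = as.integer(n_burnin), n_adapt = as.integer(n_adapt),
         thin = as.integer(thin), M = as.integer(M),
         seeds = as.integer(seeds), steps = steps,
         snapshot_every = as.integer(snapshot_every)),
    class = "mcmc_config"
  )
}

#' Fit the spatial count model by MCMC
#'
#' Runs independent Metropolis-within-Gibbs chains on the data-augmented
#' spatial count model and returns monitored draws of abundance N, density
#' D = N / area, `lambda0`, `sigma` and `psi`, plus periodic snapshots of
#' the inclusion flags and activity centres for density mapping. Each chain
#' tunes its proposal scales during an adaptive phase, then freezes them;
#' runs are bit-reproducible from the per-chain seeds.
#'
#' @param counts a [nightly_counts()].
#' @param array the matching [detector_array()].
#' @param state_space a [state_space()]; density is reported per hectare of
#'   this rectangle.
#' @param priors a [make_priors()] specification.
#' @param config an [mcmc_config()].
#' @return A `posterior_draws` object: `draws` (data frame with columns
#'   `chain`, `iteration`, `N`, `D`, `lambda0`, `sigma`, `psi`),
#'   `snapshots` (data frame `chain`, `iteration`, `individual`, `x`, `y`,
#'   `z`), the state-space, `M` and the config.
#' @seealso [gelman_rubin()], [summarize_draws()], [rasterize_density()]
#' @export
run_chains <- function(counts, array, state_space, priors,
                       config = mcmc_config()) {
  stopifnot(inherits(counts, "nightly_counts"),
            inherits(array, "detector_array"),
            inherits(state_space, "state_space"),
            inherits(priors, "prior_spec"),
            inherits(config, "mcmc_config"))
  m <- counts$counts
  if (nrow(m) != nrow(array)) {
    stop_invalid("count matrix rows must match the detector array")
  }
  if (all(is.na(m))) stop_invalid("all detector-nights are missing")
  ss <- count_sufficient_stats(counts)

  prior_list <- list(
    lambda0_lo = priors$lambda0[1], lambda0_hi = priors$lambda0[2],
    psi_a = priors$psi[1], psi_b = priors$psi[2],
    sigma_dist = if (priors$sigma$dist == "uniform") 0L else 1L,
    sigma_p1 = if (priors$sigma$dist == "uniform") priors$sigma$lo else priors$sigma$shape,
    sigma_p2 = if (priors$sigma$dist == "uniform") priors$sigma$hi else priors$sigma$rate
  )
  init_lambda0 <- max(mean(m, na.rm = TRUE) / 2, 0.05)
  init_sigma <- if (priors$sigma$dist == "gamma") {
    priors$sigma$mean
  } else {
    (priors$sigma$lo + priors$sigma$hi) / 4
  }

  draws <- vector("list", config$n_chains)
  snaps <- vector("list", config$n_chains)
  for (c in seq_len(config$n_chains)) {
    res <- with_seed(config$seeds[c], {
      run_chain_cpp(ss$n_total, ss$k_obs, trap_matrix(array),
                    c(state_space$xmin, state_space$xmax,
                      state_space$ymin, state_space$ymax),
                    state_space$area_ha, prior_list,
                    config$M, config$n_iter, config$n_burnin,
                    config$n_adapt, config$thin, config$snapshot_every,
                    as.numeric(config$steps), init_lambda0, init_sigma)
    })
    d <- as.data.frame(res$draws)
    d <- cbind(chain = c, iteration = seq_len(nrow(d)), d)
    draws[[c]] <- d
    n_snap <- length(res$snap_iter)
    snaps[[c]] <- data.frame(
      chain = c,
      iteration = rep(res$snap_iter, each = config$M),
      individual = rep(seq_len(config$M), times = n_snap),
      x = as.vector(t(res$snap_x)),
      y = as.vector(t(res$snap_y)),
      z = as.vector(t(res$snap_z))
    )
  }
  out <- structure(
    list(draws = do.call(rbind, draws),
         snapshots = do.call(rbind, snaps),
         state_space = state_space, M = config$M, config = config,
         priors = priors),
    class = "posterior_draws"
  )
  if (mean(out$draws$N == config$M) > 0.01) {
    warning("posterior abundance piles up at the augmentation ceiling M = ",
            config$M, "; increase M", call. = FALSE)
  }
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d chains x %d retained iterations (M = %d)\n",
              max(x$draws$chain), max(x$draws$iteration), x$M))
  print(summarize_draws(x))
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor from between- and within-chain
#' variances: with m chains of n draws, `W` the mean within-chain variance
#' and `B/n` the variance of the chain means, `Rhat = sqrt(((n-1)/n * W +
#' B/n) / W)`. Values below 1.1 are conventionally taken as converged.
#' Parameters with zero within-chain variance have an undefined statistic
#' and are returned as `NA`.
#'
#' @param draws a `posterior_draws` object, or a data frame with columns
#'   `chain` and the monitored parameters.
#' @param params parameters to assess.
#' @return Named numeric vector of Rhat values (`NA` where undefined).
#' @export
gelman_rubin <- function(draws, params = c("N", "D", "lambda0", "sigma", "psi")) {
  d <- if (inherits(draws, "posterior_draws")) draws$draws else as.data.frame(draws)
  params <- intersect(params, names(d))
  chains <- unique(d$chain)
  if (length(chains) < 2L) {
    stop_invalid("gelman_rubin needs at least 2 chains")
  }
  if (min(table(d$chain)) < 2L) {
    stop_invalid("gelman_rubin needs at least 2 retained iterations per chain")
  }
  vapply(params, function(p) {
    by_chain <- split(d[[p]], d$chain)
    n <- min(lengths(by_chain))
    by_chain <- lapply(by_chain, function(v) v[seq_len(n)])
    W <- mean(vapply(by_chain, stats::var, 0))
    B_over_n <- stats::var(vapply(by_chain, mean, 0))
    if (W == 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, 0)
}

#' Summarise posterior draws
#'
#' Posterior mean and central 50% credible interval (25th and 75th
#' percentiles, pooled across chains) for each monitored parameter. Density
#' D is in individuals per hectare.
#'
#' @param draws a `posterior_draws` object or compatible data frame.
#' @param params parameters to summarise.
#' @return Data frame with columns `parameter`, `mean`, `lower50`, `upper50`.
#' @export
summarize_draws <- function(draws,
                            params = c("N", "D", "lambda0", "sigma", "psi")) {
  d <- if (inherits(draws, "posterior_draws")) draws$draws else as.data.frame(draws)
  params <- intersect(params, names(d))
  if (!nrow(d)) stop_invalid("no draws to summarise")
  out <- do.call(rbind, lapply(params, function(p) {
    q <- stats::quantile(d[[p]], c(0.25, 0.75), names = FALSE)
    data.frame(parameter = p, mean = mean(d[[p]]),
               lower50 = q[1], upper50 = q[2])
  }))
  rownames(out) <- NULL
  out
}

# pooled quantile-based credible interval, used by reports
credible_interval <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE)
}
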