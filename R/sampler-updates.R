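#' Single Metropolis-within-Gibbs updates
#'
#' Reference implementations of the sampler's conditional updates, one
#' full sweep of each block per call. [run_chains()] uses a compiled
#' implementation of the identical conditionals; these R versions define the
#' sampler's semantics and back the distributional tests.
#'
#' * `update_z()`: each inclusion flag `z_i` is drawn from its exact
#'   Bernoulli full conditional, proportional to
#'   `psi^z (1-psi)^(1-z)` times the Poisson likelihood with/without
#'   individual i.
#' * `update_s()`: included individuals take a bivariate Gaussian
#'   random-walk proposal (sd `step` per coordinate), rejected outright
#'   outside the state-space (uniform prior) and otherwise accepted by a
#'   Metropolis step on the Poisson likelihood; excluded individuals
#'   (`z_i = 0`) contribute no likelihood and are redrawn uniformly over S.
#' * `update_scalars()`: `lambda0` and `sigma` move by log-scale
#'   random walks against likelihood times prior (with the log-scale
#'   Jacobian); `psi` is conjugate and drawn exactly from
#'   `Beta(a + N, b + M - N)`.
#'
#' @param state a [latent_state()].
#' @param counts a [nightly_counts()].
#' @param array the matching [detector_array()].
#' @param step random-walk sd for activity centres, metres.
#' @param priors a [make_priors()] specification.
#' @param steps named log-scale proposal sds for `lambda0` and `sigma`.
#' @return The updated `latent_state`.
#' @name sampler_updates
NULL

# Poisson log-likelihood from per-detector sufficient stats, dropping
# count-factorial constants (cancel in every ratio used here).
loglik_from_sumg <- function(n_total, k_obs, lambda0, sumg) {
  lam <- lambda0 * sumg
  ll <- 0
  obs <- k_obs > 0
  pos <- obs & n_total > 0
  if (any(pos & lam == 0)) return(-Inf)
  ll <- sum(n_total[pos] * log(lam[pos])) - sum(k_obs[obs] * lam[obs])
  ll
}

#' @rdname sampler_updates
#' @export
update_z <- function(state, counts, array) {
  ss <- count_sufficient_stats(counts)
  traps <- trap_matrix(array)
  g <- kernel_matrix(state$s, traps, state$sigma)
  z <- state$z
  sumg <- colSums(g * z)
  lpsi <- log(state$psi); l1mpsi <- log1p(-state$psi)
  for (i in seq_len(state$M)) {
    base <- pmax(sumg - z[i] * g[i, ], 0)   # guard tiny negative cancellation
    ll0 <- loglik_from_sumg(ss$n_total, ss$k_obs, state$lambda0, base)
    ll1 <- loglik_from_sumg(ss$n_total, ss$k_obs, state$lambda0, base + g[i, ])
    logit <- (lpsi + ll1) - (l1mpsi + ll0)
    p1 <- if (is.nan(logit)) 0 else stats::plogis(logit)
    z[i] <- as.integer(stats::runif(1) < p1)
    sumg <- base + z[i] * g[i, ]
  }
  state$z <- z
  state
}

#' @rdname sampler_updates
#' @export
update_s <- function(state, counts, array, step) {
  if (step <= 0) stop_invalid("step must be positive")
  ss <- count_sufficient_stats(counts)
  S <- state$state_space
  traps <- trap_matrix(array)
  g <- kernel_matrix(state$s, traps, state$sigma)
  sumg <- colSums(g * state$z)
  for (i in seq_len(state$M)) {
    if (state$z[i] == 0L) {
      state$s[i, ] <- c(stats::runif(1, S$xmin, S$xmax),
                        stats::runif(1, S$ymin, S$ymax))
      g[i, ] <- kernel_matrix(state$s[i, , drop = FALSE], traps, state$sigma)
      next
    }
    prop <- state$s[i, ] + stats::rnorm(2, 0, step)
    if (prop[1] < S$xmin || prop[1] > S$xmax ||
        prop[2] < S$ymin || prop[2] > S$ymax) next
    gp <- kernel_matrix(matrix(prop, 1), traps, state$sigma)[1, ]
    ll_cur <- loglik_from_sumg(ss$n_total, ss$k_obs, state$lambda0, sumg)
    ll_new <- loglik_from_sumg(ss$n_total, ss$k_obs, state$lambda0,
                               pmax(sumg - g[i, ] + gp, 0))
    if (log(stats::runif(1)) < ll_new - ll_cur) {
      sumg <- sumg - g[i, ] + gp
      state$s[i, ] <- prop
      g[i, ] <- gp
    }
  }
  state
}

log_sigma_prior <- function(sigma, priors) {
  sp <- priors$sigma
  if (sp$dist == "uniform") {
    if (sigma <= sp$lo || sigma >= sp$hi) -Inf else 0
  } else {
    stats::dgamma(sigma, shape = sp$shape, rate = sp$rate, log = TRUE)
  }
}

#' @rdname sampler_updates
#' @export
update_scalars <- function(state, counts, array, priors,
                           steps = c(lambda0 = 0.4, sigma = 0.15)) {
  ss <- count_sufficient_stats(counts)
  traps <- trap_matrix(array)
  g <- kernel_matrix(state$s, traps, state$sigma)
  sumg <- colSums(g * state$z)

  # lambda0: log-scale random walk, uniform prior
  l0p <- state$lambda0 * exp(stats::rnorm(1, 0, steps[["lambda0"]]))
  if (l0p > priors$lambda0[1] && l0p < priors$lambda0[2]) {
    ll_new <- loglik_from_sumg(ss$n_total, ss$k_obs, l0p, sumg)
    ll_cur <- loglik_from_sumg(ss$n_total, ss$k_obs, state$lambda0, sumg)
    lr <- if (!is.finite(ll_new)) -Inf
      else if (!is.finite(ll_cur)) Inf
      else ll_new - ll_cur + log(l0p) - log(state$lambda0)  # log-scale Jacobian
    if (log(stats::runif(1)) < lr) state$lambda0 <- l0p
  }

  # sigma: log-scale random walk against likelihood x prior
  sp <- state$sigma * exp(stats::rnorm(1, 0, steps[["sigma"]]))
  lp <- log_sigma_prior(sp, priors)
  if (is.finite(lp)) {
    sumg_p <- colSums(kernel_matrix(state$s, traps, sp) * state$z)
    ll_new <- loglik_from_sumg(ss$n_total, ss$k_obs, state$lambda0, sumg_p)
    ll_cur <- loglik_from_sumg(ss$n_total, ss$k_obs, state$lambda0, sumg)
    lr <- if (!is.finite(ll_new)) -Inf
      else if (!is.finite(ll_cur)) Inf
      else ll_new - ll_cur + lp - log_sigma_prior(state$sigma, priors) +
        log(sp) - log(state$sigma)
    if (log(stats::runif(1)) < lr) state$sigma <- sp
  }

  # psi: conjugate beta draw
  N <- sum(state$z)
  state$psi <- stats::rbeta(1, priors$psi[1] + N, priors$psi[2] + state$M - N)
  state
}
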