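#' Survey protocol for the realistic count generator
#'
#' Describes an acoustic survey the way it is actually run: sensors record
#' every night from sunset to sunrise, recordings are cut into 10-minute
#' bins, and the nightly count at a detector is the number of bins with at
#' least one detected call. Defaults emulate a two-week spring deployment
#' (~11 h nights, so 66 ten-minute periods).
#'
#' @param n_nights number of survey nights K (>= 1).
#' @param periods_per_night number of 10-minute bins per night (>= 1).
#' @param nightly_call_rate expected call bouts per individual per night.
#' @param g0 per-bout detection probability at distance zero (in `[0, 1]`).
#' @param sigma_det detection decay scale, metres (> 0).
#' @param failure_ids detector ids that recorded nothing (clock/battery
#'   failures); their rows are returned as missing.
#' @return A `survey_protocol` list.
#' @export
survey_protocol <- function(n_nights = 14, periods_per_night = 66,
                            nightly_call_rate = 10, g0 = 0.5,
                            sigma_det = 150, failure_ids = character(0)) {
  if (n_nights < 1) stop_invalid("n_nights must be >= 1")
  if (periods_per_night < 1) stop_invalid("periods_per_night must be >= 1")
  if (g0 < 0 || g0 > 1) stop_invalid("g0 must lie in [0, 1]")
  if (sigma_det <= 0) stop_invalid("sigma_det must be positive")
  if (nightly_call_rate < 0) stop_invalid("nightly_call_rate must be >= 0")
  structure(
    list(n_nights = as.integer(n_nights),
         periods_per_night = as.integer(periods_per_night),
         nightly_call_rate = nightly_call_rate,
         g0 = g0, sigma_det = sigma_det,
         failure_ids = as.character(failure_ids)),
    class = "survey_protocol"
  )
}

#' Simulate a population of activity centres
#'
#' Realises the SC model's population assumption: a Poisson number of
#' individuals (mean `density * area`) with activity centres placed
#' uniformly over the state-space.
#'
#' @param density true density in individuals per hectare (>= 0).
#' @param state_space a [state_space()].
#' @param seed optional RNG seed (the caller's RNG state is restored).
#' @return A `true_population`: list with `centres` (n x 2 matrix),
#'   `density` (realised, n / area) and the state-space.
#' @export
simulate_population <- function(density, state_space, seed = NULL) {
  if (!is.numeric(density) || density < 0) {
    stop_invalid("density must be non-negative (individuals per ha)")
  }
  with_seed(seed, {
    n <- stats::rpois(1, density * state_space$area_ha)
    centres <- cbind(
      x = stats::runif(n, state_space$xmin, state_space$xmax),
      y = stats::runif(n, state_space$ymin, state_space$ymax)
    )
    structure(
      list(centres = centres, density = n / state_space$area_ha,
           state_space = state_space),
      class = "true_population"
    )
  })
}

#' @export
print.true_population <- function(x, ...) {
  cat(sprintf("True population: %d activity centres (%.4f per ha over %.0f ha)\n",
              nrow(x$centres), x$density, x$state_space$area_ha))
  invisible(x)
}

#' Simulate counts exactly under the spatial count model
#'
#' The model-exact generator: nightly counts are independent Poisson draws
#' with detector rate `Lambda_j = lambda0 * sum_i exp(-d(s_i, x_j)^2 /
#' (2 sigma^2))`, constant across nights. Use this generator for
#' parameter-recovery experiments, where the fitted model is exactly the
#' data-generating model.
#'
#' @param pop a `true_population` from [simulate_population()].
#' @param array a [detector_array()].
#' @param lambda0 baseline encounter rate per night (>= 0).
#' @param sigma spatial scale, metres (> 0).
#' @param n_nights number of survey nights K.
#' @param seed optional RNG seed.
#' @return A [nightly_counts()] (J x K).
#' @export
simulate_counts_model_exact <- function(pop, array, lambda0, sigma,
                                        n_nights = 14, seed = NULL) {
  if (lambda0 < 0) stop_invalid("lambda0 must be non-negative")
  if (sigma <= 0) stop_invalid("sigma must be positive")
  lam <- population_rates(pop, array, lambda0, sigma)
  J <- nrow(array)
  with_seed(seed, {
    m <- matrix(stats::rpois(J * n_nights, rep(lam, n_nights)), nrow = J)
    rownames(m) <- array$detector_id
    nightly_counts(m)
  })
}

# Lambda_j for a fully-included true population
population_rates <- function(pop, array, lambda0, sigma) {
  traps <- trap_matrix(array)
  if (nrow(pop$centres) == 0) return(rep(0, nrow(traps)))
  lambda0 * colSums(kernel_matrix(pop$centres, traps, sigma))
}

#' Simulate counts under the survey protocol
#'
#' The survey-realistic generator: each individual emits a Poisson number of
#' call bouts per night, each bout falls in a uniformly chosen 10-minute
#' bin, and each bout is detected independently at detector j with
#' probability `g0 * exp(-d^2 / (2 sigma_det^2))`. The nightly count is the
#' number of bins with at least one detected bout, so counts are capped at
#' `periods_per_night` — the binning the fitted Poisson model ignores.
#' Detectors listed in `protocol$failure_ids` are returned fully missing.
#'
#' @param pop a `true_population`.
#' @param array a [detector_array()].
#' @param protocol a [survey_protocol()].
#' @param seed optional RNG seed.
#' @return A [nightly_counts()] (J x `n_nights`).
#' @export
simulate_counts_protocol <- function(pop, array, protocol, seed = NULL) {
  stopifnot(inherits(protocol, "survey_protocol"))
  unknown <- setdiff(protocol$failure_ids, array$detector_id)
  if (length(unknown)) {
    stop_invalid("failure_ids not in the array: ", paste(unknown, collapse = ", "))
  }
  traps <- trap_matrix(array)
  J <- nrow(traps)
  K <- protocol$n_nights
  B <- protocol$periods_per_night
  n_ind <- nrow(pop$centres)
  # per-individual, per-detector bout detection probabilities (J x n)
  p_det <- if (n_ind > 0) {
    protocol$g0 * t(kernel_matrix(pop$centres, traps, protocol$sigma_det))
  } else {
    matrix(0, J, 0)
  }
  with_seed(seed, {
    m <- matrix(0, J, K, dimnames = list(array$detector_id, NULL))
    for (k in seq_len(K)) {
      occupied <- matrix(FALSE, J, B)
      for (i in seq_len(n_ind)) {
        n_bouts <- stats::rpois(1, protocol$nightly_call_rate)
        if (n_bouts == 0) next
        bins <- sample.int(B, n_bouts, replace = TRUE)
        for (b in seq_len(n_bouts)) {
          heard <- stats::runif(J) < p_det[, i]
          occupied[heard, bins[b]] <- TRUE
        }
      }
      m[, k] <- rowSums(occupied)
    }
    m[array$detector_id %in% protocol$failure_ids, ] <- NA
    nightly_counts(m)
  })
}
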