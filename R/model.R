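#' State-space of activity centres
#'
#' The state-space S is the rectangle over which latent activity centres may
#' lie: the minimum bounding rectangle of the detector locations expanded by
#' a buffer on all four sides. Density is abundance divided by the
#' state-space area, so S must be wide enough that individuals outside it
#' have negligible detection probability; the motivating surveys used a
#' 750 m buffer around each array.
#'
#' @param array a [detector_array()].
#' @param buffer buffer width in metres (>= 0) added to every side.
#' @return A `state_space`: list with `xmin`, `xmax`, `ymin`, `ymax`,
#'   `buffer` (metres) and `area_ha` (hectares).
#' @examples
#' build_state_space(make_grid_array(5, 5, 400), buffer = 750)$area_ha  # 961
#' @export
build_state_space <- function(array, buffer) {
  if (!inherits(array, "detector_array") || nrow(array) < 1L) {
    stop_invalid("array must be a non-empty detector_array")
  }
  if (!is.numeric(buffer) || length(buffer) != 1L || buffer < 0) {
    stop_invalid("buffer must be a non-negative number of metres")
  }
  state_space(min(array$x) - buffer, max(array$x) + buffer,
              min(array$y) - buffer, max(array$y) + buffer,
              buffer = buffer)
}

#' @rdname build_state_space
#' @param xmin,xmax,ymin,ymax rectangle bounds in metres.
#' @export
state_space <- function(xmin, xmax, ymin, ymax, buffer = 0) {
  if (!(xmax > xmin) || !(ymax > ymin)) {
    stop_invalid("state-space must have xmax > xmin and ymax > ymin")
  }
  structure(
    list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         buffer = buffer,
         area_ha = (xmax - xmin) * (ymax - ymin) / 1e4),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("State-space: %.0f m x %.0f m (%.1f ha), buffer %.0f m\n",
              x$xmax - x$xmin, x$ymax - x$ymin, x$area_ha, x$buffer))
  invisible(x)
}

#' Half-normal encounter rate
#'
#' Expected nightly count at a detector a distance `d` from an activity
#' centre, under a Poisson encounter model with bivariate-normal movement:
#' `lambda0 * exp(-d^2 / (2 sigma^2))`. `lambda0` is the baseline encounter
#' rate (expected count when the centre sits on the detector) and `sigma`
#' the spatial decay scale, proportional to home-range radius.
#'
#' @param d distance(s) in metres (>= 0).
#' @param lambda0 baseline encounter rate per night (>= 0).
#' @param sigma spatial scale in metres (> 0).
#' @return Expected counts per night, same length as `d`.
#' @export
encounter_rate <- function(d, lambda0, sigma) {
  if (any(d < 0)) stop_invalid("distances must be non-negative")
  if (lambda0 < 0) stop_invalid("lambda0 must be non-negative")
  if (sigma <= 0) stop_invalid("sigma must be positive")
  lambda0 * exp(-d^2 / (2 * sigma^2))
}

# M x J matrix of half-normal kernel values exp(-d_ij^2 / (2 sigma^2))
# for centres s (M x 2) against traps (J x 2).
kernel_matrix <- function(s, traps, sigma) {
  d2 <- outer(s[, 1], traps[, 1], "-")^2 + outer(s[, 2], traps[, 2], "-")^2
  exp(-d2 / (2 * sigma^2))
}

# Expected count per detector: Lambda_j = lambda0 * sum_{i: z_i = 1} g_ij.
detector_rates <- function(state, traps) {
  inc <- state$z > 0
  if (!any(inc)) return(rep(0, nrow(traps)))
  g <- kernel_matrix(state$s[inc, , drop = FALSE], traps, state$sigma)
  state$lambda0 * colSums(g)
}

#' Latent augmented-model state
#'
#' One state of the data-augmented spatial count model: an oversized
#' population of `M` hypothetical individuals with inclusion flags `z`
#' (realised abundance N = sum(z)), activity centres `s`, baseline rate
#' `lambda0`, spatial scale `sigma`, and inclusion probability `psi`.
#'
#' @param M augmentation size.
#' @param z integer/logical vector of M inclusion flags.
#' @param s M x 2 matrix of activity-centre coordinates, inside `state_space`.
#' @param lambda0,sigma,psi scalar parameters.
#' @param state_space a [state_space()].
#' @return A `latent_state` list.
#' @export
latent_state <- function(M, z, s, lambda0, sigma, psi, state_space) {
  z <- as.integer(z)
  s <- as.matrix(s)
  if (length(z) != M || nrow(s) != M || ncol(s) != 2) {
    stop_invalid("z must have length M and s must be an M x 2 matrix")
  }
  if (!all(z %in% c(0L, 1L))) stop_invalid("z flags must be 0 or 1")
  if (psi < 0 || psi > 1) stop_invalid("psi must lie in [0, 1]")
  if (lambda0 < 0) stop_invalid("lambda0 must be non-negative")
  if (sigma <= 0) stop_invalid("sigma must be positive")
  inside <- s[, 1] >= state_space$xmin & s[, 1] <= state_space$xmax &
    s[, 2] >= state_space$ymin & s[, 2] <= state_space$ymax
  if (!all(inside)) stop_invalid("all activity centres must lie inside the state-space")
  structure(
    list(M = M, z = z, s = s, lambda0 = lambda0, sigma = sigma, psi = psi,
         state_space = state_space),
    class = "latent_state"
  )
}

#' Complete-data log-likelihood of the spatial count model
#'
#' Poisson likelihood of the nightly counts given a latent state: each
#' observed cell (j, k) contributes `dpois(n_jk, Lambda_j)` with
#' `Lambda_j = lambda0 * sum_i z_i exp(-d_ij^2 / (2 sigma^2))`. Rates are
#' constant across nights; missing detector-nights are excluded. Returns
#' `-Inf` only when some positive count has rate zero.
#'
#' @param counts a [nightly_counts()] with J rows.
#' @param state a [latent_state()].
#' @param array the [detector_array()] (J detectors, matching row order).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(counts, state, array) {
  m <- counts$counts
  if (nrow(m) != nrow(array)) {
    stop_invalid("count matrix rows must match the detector array")
  }
  if (any(m[!is.na(m)] < 0)) stop_invalid("counts must be non-negative")
  lam <- detector_rates(state, trap_matrix(array))
  lam_cells <- matrix(lam, nrow(m), ncol(m))
  obs <- !is.na(m)
  sum(stats::dpois(m[obs], lam_cells[obs], log = TRUE))
}

#' Spatial scale implied by a home-range area
#'
#' Converts a home-range area to the half-normal scale `sigma` under the
#' bivariate-normal home-range model: the area is the `hr_quantile` contour
#' of a circular bivariate normal, `area = pi * q * sigma^2` with `q` the
#' chi-square(2 df) quantile, so `sigma = sqrt(area_m2 / (pi * q))`. A 40 ha
#' male home range at the conventional 95% contour gives sigma of about
#' 146 m.
#'
#' @param area home-range area in hectares (> 0).
#' @param hr_quantile home-range contour probability, default 0.95.
#' @return sigma in metres.
#' @export
sigma_from_homerange <- function(area, hr_quantile = 0.95) {
  if (!is.numeric(area) || any(area <= 0)) stop_invalid("area must be positive (ha)")
  if (hr_quantile <= 0 || hr_quantile >= 1) {
    stop_invalid("hr_quantile must lie strictly between 0 and 1")
  }
  sqrt(area * 1e4 / (pi * stats::qchisq(hr_quantile, df = 2)))
}

#' Prior specifications for the spatial count model
#'
#' Builds the three prior sets used for acoustic SC fits. All share
#' `lambda0 ~ Uniform(0, 100)` and `psi ~ Beta(1, 1)`. The `sigma` prior is
#' either uniform (`"uninformative"`) or a gamma distribution moment-matched
#' to a home-range-derived mean:
#' * `"strong"`: mean from a single site-specific home-range area
#'   (`homerange_mean`, ha) with coefficient of variation `cv`;
#' * `"weak"`: mean from the midpoint of a plausible home-range range
#'   (`homerange_range`, ha) with sd spanning half the implied sigma range.
#'
#' @param label one of `"uninformative"`, `"weak"`, `"strong"`.
#' @param homerange_mean home-range area in ha (required for `"strong"`).
#' @param homerange_range length-2 min/max home-range areas in ha (required
#'   for `"weak"`).
#' @param cv coefficient of variation of the strong sigma prior.
#' @param sigma_bounds bounds (metres) of the uniform sigma prior.
#' @param lambda0_bounds bounds of the uniform lambda0 prior.
#' @param psi_shape beta shape parameters for psi.
#' @param hr_quantile home-range contour passed to [sigma_from_homerange()].
#' @return A `prior_spec` list with elements `label`, `lambda0` (`c(lo, hi)`),
#'   `psi` (`c(a, b)`) and `sigma` (`list(dist, ...)` with either `lo`/`hi`
#'   or `shape`/`rate` plus the implied `mean` and `sd`).
#' @examples
#' p <- make_priors("strong", homerange_mean = 40)
#' p$sigma$mean  # ~145.8 m
#' @export
make_priors <- function(label = c("uninformative", "weak", "strong"),
                        homerange_mean = NULL, homerange_range = NULL,
                        cv = 0.2,
                        sigma_bounds = c(0, 2000),
                        lambda0_bounds = c(0, 100),
                        psi_shape = c(1, 1),
                        hr_quantile = 0.95) {
  label <- match.arg(label)
  stopifnot(length(lambda0_bounds) == 2L, lambda0_bounds[1] < lambda0_bounds[2],
            length(psi_shape) == 2L, all(psi_shape > 0))
  sigma <- switch(label,
    uninformative = {
      if (sigma_bounds[1] >= sigma_bounds[2]) {
        stop_invalid("sigma_bounds must satisfy lo < hi")
      }
      list(dist = "uniform", lo = sigma_bounds[1], hi = sigma_bounds[2])
    },
    strong = {
      if (is.null(homerange_mean)) {
        stop_invalid("strong priors require homerange_mean (ha)")
      }
      mu <- sigma_from_homerange(homerange_mean, hr_quantile)
      gamma_prior(mu, cv * mu)
    },
    weak = {
      if (is.null(homerange_range) || length(homerange_range) != 2L) {
        stop_invalid("weak priors require homerange_range = c(min, max) in ha")
      }
      hr <- sort(as.numeric(homerange_range))
      mu <- sigma_from_homerange(mean(hr), hr_quantile)
      sd <- diff(sigma_from_homerange(hr, hr_quantile)) / 2
      gamma_prior(mu, max(sd, 1e-8))
    }
  )
  structure(
    list(label = label, lambda0 = lambda0_bounds, psi = psi_shape,
         sigma = sigma),
    class = "prior_spec"
  )
}

# moment-matched gamma: shape/rate = mean, shape/rate^2 = sd^2
gamma_prior <- function(mean, sd) {
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  list(dist = "gamma", shape = shape, rate = rate, mean = mean, sd = sd)
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Priors (%s): lambda0 ~ U(%g, %g); psi ~ Beta(%g, %g); sigma ~ %s\n",
              x$label, x$lambda0[1], x$lambda0[2], x$psi[1], x$psi[2],
              if (x$sigma$dist == "uniform") {
                sprintf("U(%g, %g) m", x$sigma$lo, x$sigma$hi)
              } else {
                sprintf("Gamma(shape %.2f, rate %.4f) [mean %.1f m, sd %.1f m]",
                        x$sigma$shape, x$sigma$rate, x$sigma$mean, x$sigma$sd)
              }))
  invisible(x)
}
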