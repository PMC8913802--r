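test_that("state-space construction buffers the array envelope", {
  ss <- build_state_space(make_grid_array(5, 5, 400), 750)
  expect_equal(ss$xmax - ss$xmin, 3100)
  expect_equal(ss$ymax - ss$ymin, 3100)
  expect_equal(ss$area_ha, 961)

  small <- build_state_space(make_grid_array(2, 2, 100), 0)
  expect_equal(small$area_ha, 1)

  a <- make_grid_array(3, 4, 250)
  expect_gt(build_state_space(a, 750)$area_ha, build_state_space(a, 0)$area_ha)
  expect_error(build_state_space(a, -1), "non-negative")
  expect_error(state_space(1, 0, 0, 1), "xmax > xmin")
})

test_that("the half-normal encounter rate has its closed-form landmarks", {
  expect_equal(encounter_rate(0, 0.7, 150), 0.7)
  expect_equal(encounter_rate(150 * sqrt(2 * log(2)), 1, 150), 0.5)
  expect_equal(encounter_rate(2 * 150, 1, 150), exp(-2), tolerance = 1e-12)
  d <- seq(0, 1000, by = 50)
  expect_true(all(diff(encounter_rate(d, 1, 150)) < 0))
  expect_error(encounter_rate(-1, 1, 150), "non-negative")
  expect_error(encounter_rate(1, 1, 0), "positive")
})

test_that("the encounter rate integrates to lambda0 * 2 pi sigma^2", {
  sigma <- 150; lambda0 <- 0.4
  h <- sigma / 20
  x <- seq(-6 * sigma, 6 * sigma, by = h)
  grid <- expand.grid(x = x, y = x)
  num <- sum(encounter_rate(sqrt(grid$x^2 + grid$y^2), lambda0, sigma)) * h^2
  expect_equal(num, lambda0 * 2 * pi * sigma^2, tolerance = 0.01)
})

test_that("home-range areas convert to sigma under the bivariate-normal model", {
  expect_equal(sigma_from_homerange(40), 145.777, tolerance = 1e-4)
  expect_equal(sigma_from_homerange(160), 2 * sigma_from_homerange(40))
  # hr_quantile with chi-square quantile 1 gives the circle-equivalent radius
  q1 <- pchisq(1, df = 2)
  expect_equal(sigma_from_homerange(40, q1), sqrt(40 * 1e4 / pi))
  expect_error(sigma_from_homerange(0), "positive")
  expect_error(sigma_from_homerange(40, 1), "strictly between")
})

test_that("prior constructors moment-match the sigma distribution", {
  strong <- make_priors("strong", homerange_mean = 40, cv = 0.2)
  expect_equal(strong$sigma$mean, sigma_from_homerange(40))
  expect_equal(strong$sigma$sd, 0.2 * sigma_from_homerange(40))
  expect_equal(strong$sigma$shape / strong$sigma$rate, strong$sigma$mean)
  expect_equal(strong$sigma$shape / strong$sigma$rate^2, strong$sigma$sd^2)
  expect_equal(strong$lambda0, c(0, 100))
  expect_equal(strong$psi, c(1, 1))

  weak <- make_priors("weak", homerange_range = c(20, 60))
  expect_equal(weak$sigma$mean, sigma_from_homerange(40))
  expect_equal(weak$sigma$sd,
               diff(sigma_from_homerange(c(20, 60))) / 2)

  flat <- make_priors("uninformative")
  expect_equal(flat$sigma$dist, "uniform")
  expect_equal(c(flat$sigma$lo, flat$sigma$hi), c(0, 2000))

  expect_error(make_priors("strong"), "homerange_mean")
  expect_error(make_priors("weak"), "homerange_range")
})

test_that("log-likelihood matches closed forms on toy states", {
  ss <- state_space(0, 1000, 0, 1000)
  a <- toy_array()

  # empty model, all counts zero: probability one
  st0 <- latent_state(2, c(0, 0), matrix(c(100, 200, 100, 200), 2),
                      lambda0 = 1, sigma = 150, psi = 0.5, state_space = ss)
  expect_equal(log_likelihood(single_detector_counts(0, a), st0, a), 0)

  # one included individual sitting on the only live detector, lambda0 = 1:
  # log Pois(k | 1) = -1 for k = 0 and k = 1
  st1 <- latent_state(1, 1, matrix(c(0, 0), 1), 1, 150, 0.5, ss)
  expect_equal(log_likelihood(single_detector_counts(0, a), st1, a), -1)
  expect_equal(log_likelihood(single_detector_counts(1, a), st1, a), -1)

  # -Inf only when a positive count has rate zero
  expect_equal(log_likelihood(single_detector_counts(1, a), st0, a), -Inf)

  bad <- single_detector_counts(0, a)
  bad$counts[1, 1] <- -1
  expect_error(log_likelihood(bad, st1, a), "non-negative")
})

test_that("log-likelihood agrees with a brute-force oracle on random states", {
  ss <- state_space(0, 500, 0, 500)
  a <- detector_array(c("A", "B"), c(100, 400), c(100, 300))
  set.seed(99)
  for (r in 1:20) {
    m <- matrix(rpois(4, 2), 2, 2)
    if (r %% 4 == 0) m[1, 2] <- NA   # masked cells must be excluded
    cnt <- counts_from_matrix(m, a)
    st <- latent_state(
      M = 2, z = rbinom(2, 1, 0.6),
      s = cbind(runif(2, 0, 500), runif(2, 0, 500)),
      lambda0 = runif(1, 0.1, 3), sigma = runif(1, 50, 300),
      psi = runif(1), state_space = ss)
    expect_loglik_match(log_likelihood(cnt, st, a),
                        brute_force_loglik(cnt, st, a))
  }
})

test_that("likelihood is invariant to relabelling and monotone in inclusion", {
  ss <- state_space(0, 1000, 0, 1000)
  a <- detector_array(c("A", "B", "C"), c(100, 500, 900), c(100, 500, 900))
  set.seed(5)
  m <- matrix(rpois(9, 1), 3, 3)
  cnt <- counts_from_matrix(m, a)
  s <- cbind(runif(4, 0, 1000), runif(4, 0, 1000))
  st <- latent_state(4, c(1, 0, 1, 0), s, 0.8, 200, 0.5, ss)

  # permuting augmented individuals
  perm <- c(3, 1, 4, 2)
  st_p <- latent_state(4, st$z[perm], s[perm, ], 0.8, 200, 0.5, ss)
  expect_equal(log_likelihood(cnt, st, a), log_likelihood(cnt, st_p, a))

  # relabelling detectors (rows permuted consistently)
  ord <- c(2, 3, 1)
  a2 <- detector_array(a$detector_id[ord], a$x[ord], a$y[ord])
  cnt2 <- counts_from_matrix(m[ord, ], a2)
  expect_equal(log_likelihood(cnt, st, a), log_likelihood(cnt2, st, a2))

  # switching an individual on never decreases any detector rate
  lam_off <- acousticSC:::detector_rates(st, acousticSC:::trap_matrix(a))
  st_on <- st; st_on$z[2] <- 1L
  lam_on <- acousticSC:::detector_rates(st_on, acousticSC:::trap_matrix(a))
  expect_true(all(lam_on >= lam_off))
})
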