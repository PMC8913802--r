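test_that("grid arrays have the right geometry and reject degenerate input", {
  a <- make_grid_array(5, 5, 400, origin = c(0, 0))
  expect_equal(nrow(a), 25)
  expect_equal(diff(range(a$x)), 1600)
  expect_equal(diff(range(a$y)), 1600)

  b <- make_grid_array(2, 3, 100, origin = c(10, 10))
  expect_equal(nrow(b), 6)
  expect_equal(max(b$x), 110)
  expect_equal(max(b$y), 210)
  expect_false(anyDuplicated(b$detector_id) > 0)

  expect_error(make_grid_array(1, 1, 400), "at least 2")
  expect_error(make_grid_array(5, 5, 0), "positive")
  expect_error(make_grid_array(5, 5, -10), "positive")
})

test_that("simulated populations are Poisson-uniform over the state-space", {
  ss <- study_state_space()
  expect_equal(ss$area_ha, 961)

  expect_equal(nrow(simulate_population(0, ss, seed = 1)$centres), 0)
  expect_error(simulate_population(-0.01, ss), "non-negative")

  # Poisson mean D * |S| = 48.05, checked over replicates within 3 MC SE
  n <- vapply(seq_len(2000), function(r) {
    nrow(simulate_population(0.05, ss, seed = 10000 + r)$centres)
  }, 0L)
  expect_lt(abs(mean(n) - 48.05), 3 * sqrt(48.05 / 2000))

  pop <- simulate_population(0.05, ss, seed = 7)
  expect_true(all(pop$centres[, 1] >= ss$xmin & pop$centres[, 1] <= ss$xmax))
  expect_true(all(pop$centres[, 2] >= ss$ymin & pop$centres[, 2] <= ss$ymax))
  expect_equal(pop$density, nrow(pop$centres) / ss$area_ha)

  # determinism contract
  expect_identical(pop$centres, simulate_population(0.05, ss, seed = 7)$centres)
})

test_that("model-exact counts have the half-normal Poisson structure", {
  ss <- study_state_space()
  a <- make_grid_array(2, 2, 400, origin = c(600, 600))

  pop <- fixed_population(c(600, 900, 1000, 600, 700, 1100), ss)
  zero <- simulate_counts_model_exact(pop, a, lambda0 = 0, sigma = 150,
                                      n_nights = 5, seed = 1)
  expect_true(all(zero$counts == 0))

  # one individual at 2 sigma from a detector: mean count -> exp(-2)
  lone <- fixed_population(c(600 + 2 * 150, 600), ss)
  cnt <- simulate_counts_model_exact(lone, a, lambda0 = 1, sigma = 150,
                                     n_nights = 10000, seed = 2)
  expect_lt(abs(mean(cnt$counts[1, ]) - exp(-2)), 3 * sqrt(exp(-2) / 10000))

  # empirical detector means match Lambda_j within 3 MC SE at every detector
  lam <- 0.5 * colSums(exp(-(outer(pop$centres[, 1], a$x, "-")^2 +
                             outer(pop$centres[, 2], a$y, "-")^2) / (2 * 150^2)))
  cnt2 <- simulate_counts_model_exact(pop, a, lambda0 = 0.5, sigma = 150,
                                      n_nights = 6000, seed = 3)
  expect_true(all(abs(rowMeans(cnt2$counts) - lam) < 3 * sqrt(lam / 6000)))
})

test_that("protocol counts respect the binning cap and the failure mask", {
  ss <- study_state_space()
  a <- study_array()
  pop <- simulate_population(0.05, ss, seed = 11)

  deaf <- survey_protocol(n_nights = 4, g0 = 0)
  expect_true(all(simulate_counts_protocol(pop, a, deaf, seed = 1)$counts == 0))

  # binary cap with a single 10-min period per night
  one_bin <- survey_protocol(n_nights = 4, periods_per_night = 1,
                             nightly_call_rate = 30, g0 = 1)
  cnt <- simulate_counts_protocol(pop, a, one_bin, seed = 2)
  expect_true(all(cnt$counts %in% c(0, 1)))

  # counts never exceed periods_per_night even at saturating rates
  busy <- survey_protocol(n_nights = 3, periods_per_night = 5,
                          nightly_call_rate = 200, g0 = 1, sigma_det = 2000)
  expect_true(all(simulate_counts_protocol(pop, a, busy, seed = 3)$counts <= 5))

  # masking contract: identical matrices except the failed row
  proto <- survey_protocol(n_nights = 5)
  full <- simulate_counts_protocol(pop, a, proto, seed = 4)
  part <- simulate_counts_protocol(
    pop, a, survey_protocol(n_nights = 5, failure_ids = "D007"), seed = 4)
  expect_true(all(is.na(part$counts["D007", ])))
  keep <- setdiff(a$detector_id, "D007")
  expect_identical(full$counts[keep, ], part$counts[keep, ])

  expect_error(
    simulate_counts_protocol(pop, a,
                             survey_protocol(failure_ids = "nope"), seed = 1),
    "failure_ids")
})

test_that("expected counts are monotone in population size", {
  ss <- study_state_space()
  a <- study_array()
  base <- simulate_population(0.03, ss, seed = 21)
  extra <- simulate_population(0.02, ss, seed = 22)
  bigger <- fixed_population(rbind(base$centres, extra$centres), ss)
  lam_tot <- function(pop) {
    sum(0.3 * exp(-(outer(pop$centres[, 1], a$x, "-")^2 +
                    outer(pop$centres[, 2], a$y, "-")^2) / (2 * 150^2)))
  }
  expect_gte(lam_tot(bigger), lam_tot(base))
})
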