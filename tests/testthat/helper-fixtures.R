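# Shared fixture builders. Everything is generated in code; no stored data.

# A population with hand-placed activity centres (bypasses the Poisson draw).
fixed_population <- function(centres, state_space) {
  centres <- matrix(centres, ncol = 2, dimnames = list(NULL, c("x", "y")))
  structure(
    list(centres = centres, density = nrow(centres) / state_space$area_ha,
         state_space = state_space),
    class = "true_population"
  )
}

# Counts from a plain matrix, detector ids defaulted to the array's.
counts_from_matrix <- function(m, array) {
  rownames(m) <- array$detector_id
  nightly_counts(m)
}

# Tiny two-detector array; mask the second row entirely to emulate the
# single-detector toys used by the closed-form conditionals.
toy_array <- function(spacing = 100) {
  detector_array(c("A", "B"), c(0, spacing), c(0, 0))
}

single_detector_counts <- function(n, array, n_nights = length(n)) {
  m <- matrix(NA_real_, 2, n_nights)
  m[1, ] <- n
  counts_from_matrix(m, array)
}

# Independent brute-force oracle for the complete-data likelihood:
# plain loops, no shared code with log_likelihood().
brute_force_loglik <- function(counts, state, array) {
  m <- counts$counts
  total <- 0
  for (j in seq_len(nrow(m))) {
    lam <- 0
    for (i in seq_len(state$M)) {
      if (state$z[i] == 1) {
        d2 <- (state$s[i, 1] - array$x[j])^2 + (state$s[i, 2] - array$y[j])^2
        lam <- lam + state$lambda0 * exp(-d2 / (2 * state$sigma^2))
      }
    }
    for (k in seq_len(ncol(m))) {
      if (!is.na(m[j, k])) total <- total + dpois(m[j, k], lam, log = TRUE)
    }
  }
  total
}

# Log-likelihoods agree either exactly (both -Inf, a positive count with a
# zero rate) or to within tol.
expect_loglik_match <- function(a, b, tol = 1e-10) {
  if (identical(a, b)) expect_identical(a, b) else expect_lt(abs(a - b), tol)
}

# Standard desk-scale study conditions used across recovery tests.
study_array <- function() make_grid_array(5, 5, 400)
study_state_space <- function() build_state_space(study_array(), 750)
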