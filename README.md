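# acousticSC

Density estimation for unmarked, vocal animals from arrays of passive
acoustic sensors, with spatial count (SC) models fitted by Bayesian data
augmentation. The package was built around surveys of male koalas in
production forests — grids of song meters record bellowing through the
night, counts of occupied 10-minute periods per night are modelled per
sensor, and density is estimated without ever identifying individuals — but
the machinery applies to any acoustic array with spatially correlated
counts.

## The model

Nightly counts `n_jk` at detector `j` on night `k` are Poisson with a rate
that decays with distance from latent activity centres:

    n_jk ~ Poisson(Λ_j),   Λ_j = λ0 Σ_i z_i exp(−d(s_i, x_j)² / (2σ²))

* `s_i` — activity (home-range) centre of individual `i`, uniform over a
  rectangular state-space `S` (the detector envelope plus a buffer,
  750 m by default);
* `z_i ∈ {0, 1}` — data-augmentation inclusion flags over an oversized
  population of size `M`, with `z_i ~ Bernoulli(ψ)`; abundance is
  `N = Σ z_i` and density `D = N / |S|`;
* `λ0` — baseline encounter rate (expected nightly count at distance 0);
* `σ` — half-normal spatial scale, proportional to home-range radius; a
  bivariate-normal home range of area `A` at the 95% contour implies
  `σ = sqrt(A / (π · χ²₂(0.95)))`, so 40 ha gives σ ≈ 146 m.

Priors follow acoustic-SC practice: `λ0 ~ U(0, 100)`, `ψ ~ Beta(1, 1)`, and
σ either uniform (uninformative) or gamma moment-matched to a
home-range-derived mean (weakly/strongly informative). Fitting is by
Metropolis-within-Gibbs: exact Bernoulli conditionals for `z`, conjugate
beta for `ψ`, random-walk moves for centres, log-scale Metropolis for `λ0`
and `σ`, with proposal scales adapted only during a declared adaptive phase.
Convergence is assessed with the Gelman–Rubin statistic (R̂ < 1.1).

Around the model sit a synthetic survey generator (model-exact and
survey-protocol variants), posterior density surfaces with forest-category
overlays, and BACIPS (Before–After-Control-Impact Paired Series) tests for
intervention effects such as timber harvesting.

## Worked example

```r
library(acousticSC)

array  <- make_grid_array(5, 5, spacing = 400)      # 25 sensors, 1600 m envelope
ss     <- build_state_space(array, buffer = 750)    # 3100 m x 3100 m, 961 ha
pop    <- simulate_population(density = 0.05, ss, seed = 42)
counts <- simulate_counts_model_exact(pop, array, lambda0 = 0.3, sigma = 150,
                                      n_nights = 14, seed = 43)
priors <- make_priors("strong", homerange_mean = 40)
fit    <- run_chains(counts, array, ss, priors, mcmc_config(seed = 1))
summarize_draws(fit)
round(gelman_rubin(fit), 3)
```

```
  parameter         mean      lower50      upper50
1         N  59.00208333  41.00000000  72.00000000
2         D   0.06139655   0.04266389   0.07492196
3   lambda0   0.53470165   0.41908512   0.62576545
4     sigma 131.09780466 117.24616465 143.74579557
5       psi   0.39472202   0.27326820   0.48686208

      N       D lambda0   sigma     psi
  1.005   1.005   1.003   1.015   1.004
```

The simulated truth was 57 activity centres (0.059 per ha); the posterior
mean density 0.061 per ha with a 50% credible interval (0.043, 0.075)
brackets it, and every R̂ is well below 1.1. `rasterize_density(fit)` turns
the retained activity-centre snapshots into a males-per-hectare pixel
surface whose total mass equals posterior mean abundance exactly, and
`category_density()` averages it over labelled forest polygons.

The harvest-effect analysis runs on array-level densities:

```r
d <- paired_design(
  pair              = c("wauchope", "kempsey", "coffs"),
  control_before    = c(0.062, 0.041, 0.055),
  treatment_before  = c(0.050, 0.042, 0.049),
  control_after     = c(0.066, 0.044, 0.053),
  treatment_after   = c(0.043, 0.037, 0.048))
bacips_test(d)
```

```
BACIPS paired t test: 3 pairs
  mean control-minus-treatment difference: 0.0087 per ha
  mean change (after - before): 0.0060 per ha
  t = 1.664, df = 2, two-sided p = 0.2380
```

A shell workflow (`simulate`, `fit`, `surface`, `bacips`, `report`) wraps
the same functions; see `?sc_cli` and the wrapper script in `inst/cli/`.

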