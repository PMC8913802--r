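---
title: "Spatial count models for acoustic arrays: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial count models for acoustic arrays: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acousticSC)
```

This vignette is the package's own account of the statistics it implements:
the model and its assumptions, the tunable parameters and their defaults,
what the synthetic generators do and do not emulate, the numerical choices,
and the known limitations. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The spatial count model

Acoustic sensors cannot tell individuals apart, so classical spatial
capture–recapture is unavailable. The spatial count (SC) model instead
exploits spatial correlation in counts across a detector array: a caller
near two adjacent sensors inflates both of their counts, and the joint
pattern across the grid is informative about how many callers there are and
roughly where they sit.

The observation unit is a detector-night. For koala surveys the nightly
count is the number of 10-minute periods with at least one validated
bellow — a bounded, de-duplicated index of calling activity. The model
treats these as Poisson:

$$n_{jk} \sim \text{Poisson}(\Lambda_j), \qquad
  \Lambda_j = \lambda_0 \sum_{i=1}^{M} z_i
  \exp\!\left(-\frac{d(s_i, x_j)^2}{2\sigma^2}\right)$$

with activity centres $s_i$ uniform over a rectangular state-space $S$,
inclusion flags $z_i \sim \text{Bernoulli}(\psi)$ over an augmented
population of size $M$, abundance $N = \sum_i z_i$ and density
$D = N/|S|$. The half-normal kernel is the encounter rate implied by
bivariate-normal movement about a home-range centre.

Assumptions worth keeping in view:

* **Closure and night-constant rates.** $\Lambda_j$ is constant across
  nights: no weather, lunar or behavioural covariates. Survey occasions
  enter only as replicate counts, which matches a two-week breeding-season
  deployment that already excludes rain/wind nights from validation.
* **Uniform centres.** The state-space is the detector envelope plus a
  buffer (default 750 m, roughly five home-range sigmas) and centres are
  uniform over it. Density estimates scale inversely with $|S|$, so the
  buffer is a real modelling choice, not plumbing.
* **Poisson counts.** The real protocol caps counts at the number of
  10-minute bins per night; the model ignores the cap. The protocol
  generator (below) exists precisely to probe that mismatch.

## Priors

`make_priors()` builds the three prior sets used in acoustic SC practice.
All share $\lambda_0 \sim U(0, 100)$ (expected calls per detector-night at
distance zero) and $\psi \sim \text{Beta}(1, 1)$.

For $\sigma$ the choice matters, because unmarked models lean on it:

* **uninformative** — $\sigma \sim U(0, 2000)$ m. A uniform upper bound
  must be supplied in metres; 2000 m is far above any plausible koala
  home-range scale, so it is effectively flat over the support that the
  likelihood visits.
* **strong** — a gamma prior moment-matched to the $\sigma$ implied by a
  single site-specific mean male home range (default 40 ha), with
  coefficient of variation 0.2. The conversion uses the 95% contour of a
  circular bivariate-normal home range, $A = \pi \chi^2_{2,0.95}
  \sigma^2$, the standard SCR convention consistent with half-normal
  encounter; 40 ha gives $\sigma \approx 145.8$ m
  (`sigma_from_homerange(40)`).
* **weak** — the same construction applied to a plausible min–max
  home-range range: the mean comes from the midpoint area, and the sd is
  set to half the spread between the $\sigma$ implied by the two
  endpoints. This is one reasonable reading of "weakly informative"; the
  gamma shape/rate are always reported in the returned object so the
  actual prior is explicit.

The gamma is parameterised by moment matching (shape $= 1/\text{cv}^2$,
rate $=$ shape/mean); published acoustic-SC analyses name a gamma but not
its hyperparameters, so making the (mean, cv) explicit seemed preferable to
guessing theirs.

## The sampler

`run_chains()` runs independent Metropolis-within-Gibbs chains (compiled
core; the exported `update_z()`, `update_s()`, `update_scalars()` are
reference R implementations of the identical conditionals, kept as the
testable definition of the sampler's semantics):

* $z_i$: exact Bernoulli full conditionals, swept sequentially;
* $\psi$: conjugate, $\text{Beta}(a + N,\, b + M - N)$;
* $s_i$: per-individual Gaussian random walks, rejected outside $S$
  (uniform prior); excluded individuals ($z_i = 0$) have no likelihood
  contribution and are redrawn uniformly over $S$, which keeps the
  augmented pool well mixed;
* $\lambda_0, \sigma$: random walks on the log scale (hence always
  positive) against likelihood × prior, with the log-scale Jacobian.

Proposal scales adapt toward acceptance rates in 0.2–0.45 during a declared
adaptive phase only (Robbins–Monro-style batch updates, default 1,000
iterations), then freeze, preserving detailed balance for every retained
draw. Chains are bit-reproducible from their seeds.

Default settings are desk-scale — $M = 150$, 3 chains × 5,000 iterations
with 1,000 burn-in, no thinning — chosen so that a full
parameter-recovery experiment (ten simulated surveys, thirty chains) runs
in about a minute while still satisfying R̂ < 1.1 on model-exact data.
Full survey-scale settings ($M = 500$, 50,000 iterations, 10,000 burn-in)
are one `mcmc_config()` call away. $M$ is a hard ceiling on $N$; the
package warns when more than 1% of posterior mass sits exactly at $M$.

Correctness is checked three independent ways in the test suite: a
brute-force product-of-Poisson oracle for the likelihood, closed-form
distributional checks on each conditional, a successive-conditional
(Geweke-style) joint-distribution test, and an end-to-end comparison of
posterior means against an independent fit of the identical model in JAGS.

## Synthetic surveys

Two generators are deliberate, separate objects:

* `simulate_counts_model_exact()` draws counts exactly from the SC model.
  Use it for parameter recovery: any estimation bias seen with it is
  attributable to the model/prior/sampler, not to data mismatch.
* `simulate_counts_protocol()` emulates the survey as run: each individual
  emits a Poisson number of call bouts per night (default 10), each bout
  lands in one of 66 ten-minute bins (a ~11 h sunset-to-sunrise night),
  and each bout is heard at detector $j$ with probability
  $g_0 e^{-d^2/2\sigma_d^2}$ (defaults $g_0 = 0.5$, $\sigma_d = 150$ m,
  bracketing the 100–300 m audibility of bellows). The nightly count is
  the number of occupied bins, capped at 66; failed sensors are returned
  fully missing.

The protocol defaults are plausible rather than calibrated: published
array-level summaries (1.4–8.9 occupied periods per night, averaged over
sensors) constrain but do not identify per-individual bout rates. The
defaults were fixed once, from that bracket, before any recovery experiment
was run, and are not tuning knobs.

What the generators do **not** emulate: false positives from the call
recogniser, night-to-night weather effects, attraction/avoidance between
callers, and non-uniform centre placement. Passing recovery tests therefore
demonstrate internal consistency of model and sampler, not robustness to
every field reality.

## Density surfaces and category overlays

`rasterize_density()` bins the retained $(z, s)$ snapshots: a pixel's value
is the snapshot-mean count of included centres inside it divided by the
pixel area (ha). No smoothing is applied beyond the posterior spread of the
centres themselves, so total raster mass equals snapshot-mean abundance
exactly (asserted to 1e−9 in the tests). The default 100 m pixel is well
below the 400 m detector spacing but coarse enough that single pixels are
not over-interpreted — these surfaces are meaningful averaged over blocks,
not patch by patch.

`category_density()` assigns pixels to polygons by pixel-centre-in-polygon
(even-odd rule, no area weighting — the simplest reproducible rule at this
resolution), averages pixels within polygons, then polygons within
categories, with a standard error from the among-polygon spread
($sd/\sqrt{n_{\text{poly}}}$; undefined and reported `NA` for
single-polygon categories). Polygons too small to contain a pixel centre
are excluded with a warning rather than silently zeroed.

## Design statistics

`harvest_intensity()` is volume/area (m³ ha⁻¹), with report-table rounding
half away from zero. `naive_occupancy()` is the percentage of *working*
detectors with any detection — failed sensors leave the denominator.

`bacips_test()` implements the paired-series BACI test: the replicate is
the control-minus-treatment density difference at a sampling period, and
the statistic is the paired $t$ on per-pair changes (after − before),
df = pairs − 1. The literature sometimes words this as a "two-sample" test
of Before vs After differences; with one before and one after period the
paired form is what yields df = n − 1, so it is the default, and a
pooled-variance two-sample form is available as an option. Degenerate
inputs are reported, not hidden: identical changes in every pair give an
undefined $t$ (`NA` plus a note), except the fully-null case (no change
anywhere) which is reported as $t = 0$, $p = 1$.

## Numerical choices and degenerate inputs

* Half-normal kernels underflow to exactly 0 beyond ~40σ; a positive count
  with a zero rate correctly yields a −∞ log-likelihood, and the samplers
  treat "current state impossible" as an automatic accept of any possible
  proposal.
* Incremental rate bookkeeping (`Λ` maintained under single-individual
  toggles) clamps tiny negative cancellation residues to zero.
* The Gelman–Rubin statistic is the classic
  $\sqrt{((n-1)/n\,W + B/n)/W}$; zero within-chain variance is undefined
  and returned `NA`, and fewer than two chains is an error.
* Credible intervals use R's default (type-7) quantiles; the 50% interval
  on draws 1..100 is (25.75, 75.25).
* Missingness is explicit: failed detector-nights are `NA` in the count
  matrix and a sidecar mask CSV on disk, never sentinel zeros. An all-missing
  matrix is rejected by `run_chains()`.
* Rasters may use a pixel size that does not divide the state-space
  extent; edge pixels then overhang outward and mass conservation is
  unaffected.

## Known limitations

* **Posterior-mean density is biased upward when data are weak.** With a
  low baseline rate (λ0 ≈ 0.3 per night), a single 25-sensor array and a
  flat ψ prior — whose induced prior on $N$ is uniform on $0..M$ — the
  $\lambda_0 \times N$ likelihood ridge leaves a long right tail on $N$.
  In the package's own recovery experiment the 95% interval covers the
  true density in 10/10 replicates and R̂ < 1.1 throughout, but the
  posterior *mean* density overshoots truth by roughly 40% on average;
  an independent JAGS fit of the identical model on the same data
  reproduces the same posterior, so this is a property of the model at
  these survey conditions, not of the sampler. Report interval summaries
  (the package's default print shows mean and 50% interval; medians are one
  `quantile()` away), use informative σ priors, and treat posterior means
  of weakly-identified fits with caution.
* Unmarked SC models cannot separate one loud caller from two quiet ones;
  λ0 and N trade off, and only spatial correlation plus priors break the
  tie.
* The state-space is a rectangle; irregular survey envelopes (rivers,
  tenure boundaries) are not representable, which inflates $|S|$ and
  deflates $D$ for strongly non-rectangular arrays.
* Counts are assumed independent across nights given the rates; pseudo-
  replication from multi-night calling bouts is not modelled.
* No false-positive model: validated counts are taken at face value.
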