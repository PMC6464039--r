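---
title: "Stabilizing small-area age-standardized rates with empirical Bayes smoothing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilizing small-area age-standardized rates with empirical Bayes smoothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratestab)
```

## The problem

Age-standardized event rates (mortality, disease prevalence) for small
geographic units — census tracts, sparsely populated counties, demographic
subgroups — are notoriously unstable: with a handful of events, the crude
rate `y/n` swings wildly between periods and between neighboring areas, and
a single death in a small age stratum can dominate the standardized rate.
`ratestab` stabilizes these estimates by smoothing the *age-specific* rates
with a conjugate empirical Bayes model before standardizing, so that the
uncertainty of the smoothed age-specific rates propagates into the
age-standardized rate, its credible interval, and a reliability alert.

## The model

For region $i$ and age group $j$, with $y_{ij}$ observed events and
$n_{ij}$ person-years at risk,

$$y_{ij} \mid \theta_{ij} \sim \mathrm{Poisson}(n_{ij}\,\theta_{ij}),
\qquad
\theta_{ij} \sim \mathrm{Gamma}(t_{ij} m_j,\; m_j),$$

in the rate parameterization, so the prior mean is the *smoothing target*
$t_{ij}$ and the prior carries the information of $m_j$ person-years of
observation. Conjugacy gives the closed-form posterior

$$\theta_{ij} \mid y_{ij} \sim \mathrm{Gamma}(y_{ij} + t_{ij} m_j,\;
n_{ij} + m_j),$$

whose mean is the precision-weighted compromise
$\frac{n_{ij}}{n_{ij}+m_j}\frac{y_{ij}}{n_{ij}} +
\frac{m_j}{n_{ij}+m_j} t_{ij}$: data-rich cells keep their crude rate,
data-poor cells are pulled toward the target.

Two targets are offered:

* **nonspatial** — $t_{ij} = r_j$, the pooled crude rate of the whole
  spatial domain for age group $j$;
* **spatial** — $t_{ij}$ is the pooled crude rate of region $i$'s
  contiguous neighbors (the focal region excluded), built from a queen- or
  rook-contiguity neighborhood dictionary.

The age-standardized rate is the weighted average
$R_i = \sum_j w_j\,\theta_{ij}$ with $w_j$ the standard population's age
distribution. Its posterior has no convenient closed form, so we sample
each $\theta_{ij}$ from its gamma posterior (age groups are conditionally
independent by construction) and summarize the weighted sums: the point
estimate is the Monte Carlo mean and the 95% interval the empirical
2.5/97.5 percentiles.

An estimate is flagged **unreliable** when its 95% interval is wider than
the estimate itself, and each region is classed as significantly
`higher` / `lower` / `not_different` relative to a reference rate according
to whether its interval excludes the reference. A wide interval can still
lie entirely below the reference, so an unreliable estimate may
nevertheless be significantly low.

## Tunable parameters

* **Prior weight `m_j`** (person-years): the predetermined degree of
  smoothing. Default: the across-region *median* of `n[, j]`, i.e. the
  prior counts as much as one typical region. This keeps the degree of
  smoothing data-independent in the sense that it does not chase any
  region's outcome, and it scales naturally per age group. Override via
  `prior_weight` when more or less shrinkage is wanted; `m -> 0` recovers
  the crude rates, `m -> Inf` collapses every region onto its target.
* **Zero targets**: a gamma prior cannot be centered at 0. When an age
  group has no events in the relevant pool, the target falls back to the
  half-event pseudo-rate `0.5 / sum_i n[i, j]`; a neighborhood with no
  usable signal (island region, zero person-years, zero events) falls back
  to the domain rate first.
* **Monte Carlo size `n_draws`** (default 10,000) and `seed` (default 42):
  at 10,000 draws the Monte Carlo standard error of the standardized-rate
  mean is about 1% of its posterior standard deviation — negligible
  relative to the intervals themselves. Draws are reproducible bit-for-bit
  given the seed, and the sampler restores the caller's RNG state.
* **Contiguity rule** (default queen, tolerance 1e-9 coordinate units):
  queen counts any shared boundary point, which is the safer default for
  census-tract layers where near-point contacts are common; rook requires
  a shared edge of positive length.
* **Output scale** (default per 100,000 person-years): purely
  presentational; all computation is in events per person-year, and alerts
  and significance classes are scale-invariant.
* **Reference rate** for the significance classes: the domain's crude
  age-standardized rate $\sum_j w_j r_j$. A population-weighted mean of
  region rates would be an alternative reading of "the regional rate"; the
  pooled rate was chosen because it is the natural fixed benchmark already
  used as the nonspatial smoothing target and does not depend on the
  smoothing method under test. The reference is treated as fixed; its own
  sampling error is not propagated.

## The simulation harness

`make_scenario()` builds a synthetic study emulating small-area
chronic-disease mortality: a 10 x 10 lattice of regions, six adult age
groups (35-44 through 85+), per-cell person-years log-uniform on
[500, 50,000] (mixing data-rich and data-poor cells), and true
age-specific rates

$$\lambda_{ij} = \beta_j \, e^{g_i}, \qquad
g_i = 0.15\,u_i + \varepsilon_i,\ \varepsilon_i \sim N(0, 0.09^2),$$

with $\beta_j$ spanning 1e-4 to 2e-2 events per person-year (heart-disease
magnitudes), $u_i$ a diagonal coordinate scaled to $[-1, 1]$, and the
region effect $g_i$ shared across age groups so rates rise with age in
every region while varying smoothly in space — giving the spatial smoother
genuine signal.

The variation amplitude was a design choice with a calibration argument
behind it: a simulation meant to measure interval coverage should be
*well-specified* for the estimator under study, meaning the between-region
spread of true rates is comparable to the prior dispersion the smoother
assumes. At the default prior weight (median person-years, about 5,000)
the prior coefficient of variation for the oldest — and, for the
standardized rate, most informative — age group is
$1/\sqrt{t_J m} \approx 0.1$; the total region-effect standard deviation
(gradient plus noise, about 0.11) was set to match it, with the split
between structured gradient (0.15 half-range) and unstructured noise
(sd 0.09) fixed so that *both* the domain-mean-targeted and the
neighborhood-targeted smoother see truth dispersion consistent with their
priors: the nonspatial smoother's bias is driven by the total spread
around the domain mean, the spatial smoother's by the unstructured part a
neighborhood average cannot track. The split was verified with pilot runs
across several master seeds at reduced replicate counts before the
defaults were fixed. Substantially larger true variation makes both sets of intervals
anti-conservative (the classical weakness of globally shrunk estimates);
substantially smaller makes them conservative.

`run_study()` then simulates `n_replicates` (default 100) independent
Poisson count datasets, estimates each with the unsmoothed, nonspatial,
and spatial methods, and reports per-region rMSE
$\sqrt{\mathrm{mean}_r (\hat R_i^{(r)} - R_i)^2}$ against the true
standardized rate, plus 95% interval coverage pooled over regions and
replicates (and per region, since pooled and per-region averaging can
differ in principle; with a complete design they coincide up to weighting).

What the harness does *not* emulate: irregular real-world geographies
(it uses a rectangular lattice), covariance between age groups beyond the
shared region effect, age structures correlated with deprivation,
overdispersion relative to Poisson counts, and suppressed or coarsened
counts in public-use data. Passing coverage and rMSE checks on this
scenario therefore demonstrates internal statistical validity of the
method under its own assumptions, not performance guarantees on any
particular real dataset — on real data where true between-region variation
exceeds the prior dispersion, intervals will undercover.

## Numerical choices

* All rates are computed in events per person-year; scaling to "per
  100,000" happens only at output.
* Credible intervals for single gamma posteriors use `qgamma` directly;
  only the standardized weighted sum needs Monte Carlo.
* Replicate and draw seeds are derived deterministically from the master
  seed (kept inside the 32-bit integer range), so an entire study is
  reproducible from one integer.
* Ties in the reliability rule (`width == estimate`) count as reliable;
  the flag fires only when the width strictly exceeds the estimate.
* Events exactly on a bin boundary belong to the upper bin
  (closed-open intervals, `"35-44"` = [35, 45)).
* Duplicate population rows are an error rather than being summed;
  ambiguous denominators are more dangerous than inconvenient input
  requirements.
* Multi-year analyses multiply the population by `observation_years`
  (user-specified, default 1) to form person-years; whether a supplied
  population is a mid-period snapshot or already person-years is the
  user's declaration, not something the package guesses.

## Known limitations

* The degree of smoothing is predetermined, not estimated; there is no
  hyperparameter learning and no fully Bayesian spatial model (e.g. a CAR
  prior fitted by MCMC), which would propagate uncertainty in the
  smoothing targets themselves.
* Record-level input only; aggregate tables with suppressed small counts
  are not handled.
* Geometry input is GeoJSON (or a precomputed adjacency JSON); the
  contiguity routine assumes clean, non-overlapping polygon layers and a
  planar coordinate system.
* Survey-weighted data are out of scope.

## A worked example

```{r, eval = FALSE}
library(ratestab)

# synthetic record-level dataset on a 4 x 4 grid
paths <- make_fixture("fixture", nrow = 4, ncol = 4, seed = 1)

est <- run_pipeline(paths$events, paths$population, paths$standard,
                    out = "results.csv",
                    age_breaks = c(35, 45, 55, 65, 75, 85),
                    geometry = paths$geometry, method = "both",
                    n_draws = 10000, seed = 42)
head(est)

# the simulation study behind the rMSE and coverage claims
res <- run_study(make_scenario(seed = 42))
res$mean_rmse
res$coverage
```
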