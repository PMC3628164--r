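---
title: "Methods: geostatistical HbC mapping and newborn burden estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geostatistical HbC mapping and newborn burden estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbcmap)
```

## The problem

Population surveys of haemoglobin C report genotype counts (AA/AC/CC)
at scattered, georeferenced locations with wildly uneven sample sizes —
from a handful of individuals to millions — and a large fraction of
surveys observing no variant at all. The aim is a continuous
allele-frequency map with calibrated uncertainty, and per-country
estimates of the annual number of AC and CC newborns. This vignette
documents the model, the conventions and the deliberate design choices;
every empirical statement here is one the package's own tests or the
acceptance script computes.

## Data model and survey handling

A survey carries coordinates (decimal degrees, WGS84), a year, genotype
counts, a diagnostic method label and a representativeness flag. Counts
are reduced to allele counts `pos = 2 n_CC + n_AC`,
`neg = 2 n_AA + n_AC`; surveys reporting complete absence of variants
are treated as all-AA. Surveys reporting only an allele frequency and a
sample size are accepted by back-computing `pos = round(2 n q)` and are
flagged in the collection's provenance. Surveys reporting phenotype
(carrier) rates without genotype resolution are *not* accepted: the
conversion would need method-specific assumptions the data model cannot
verify, so only genotype or allele counts enter.

When several surveys share a location, one is kept. "Same location"
means equality of coordinates after rounding to 4 decimal places
(roughly 11 m); merging within a radius is deliberately not done, since
it would silently blend distinct communities. The retained survey is
chosen lexicographically: larger sample size, then more recent year,
then diagnostic method (molecular assays over HPLC/IEF over
electrophoresis over unknown, configurable), then first occurrence.
The ranking is deterministic, and dropped rows are logged. These
criteria are a package decision: survey-database practice names the
relevant factors but no weighting, and a lexicographic order is the
only choice that is fully reproducible without a scoring model.

## The geostatistical model

At site $i$ with $N_i = 2 n_i$ alleles,

$$\mathrm{pos}_i \sim \mathrm{Binomial}(N_i,\ \mathrm{logit}^{-1}(\mu + f(s_i)))$$

with $f$ a zero-mean stationary, isotropic Gaussian process over
great-circle distance (haversine, sphere radius 6371.0088 km) with
covariance

$$C(d) = \sigma^2\,\rho_\nu(d/\phi) + \tau^2\,\mathbf 1(d = 0),$$

a Matérn correlation $\rho_\nu$ in the $\sqrt{2\nu}$ length-scale
convention (so $\nu = 1/2$ gives $e^{-d/\phi}$). The logit link is the
standard choice for frequency mapping and is the package's own: all
latent-scale quantities are logits of frequency.

Defaults, all configurable through `mbg_config()`:

| parameter | meaning | unit | default prior |
|---|---|---|---|
| $\mu$ | logit-scale mean | — | Normal(logit(0.01), 2²) |
| $\sigma^2$ (sill) | process variance | logit² | Exponential(rate 1) |
| $\phi$ (range) | correlation decay | km | Exponential(mean 500) |
| $\tau^2$ (nugget) | micro-scale variance | logit² | Exponential(rate 10) |
| $\nu$ (smoothness) | Matérn order | — | fixed at 3/2 (1/2, 5/2 selectable) |

The priors are weakly informative for a rare variant with
continental-scale structure; they are artifact choices, stated as such,
not published values. Matérn 3/2 is the common middle ground in
model-based geostatistics: rougher than the squared exponential,
smoother than the exponential. Any subset of $(\mu, \sigma^2, \phi,
\tau^2)$ can be held fixed via `fixed =`, which is also how the
spatial component is disabled (`sill = 0`) for oracle testing.

### Sampler

Metropolis-within-Gibbs:

* the latent vector $f$ updates by **elliptical slice sampling**, which
  needs no step tuning and is exact for the Gaussian prior;
* $\mu$ updates by a random-walk step on the binomial likelihood plus a
  likelihood-invariant *translation* move ($\mu \to \mu + \delta$,
  $f \to f - \delta$, scored by the field prior) — without the second
  move, $\mu$ and the field mean are nearly confounded and mix slowly;
* each covariance parameter takes an **interweaved pair** of log-scale
  random-walk updates: one centred (scored by the Gaussian density of
  $f$), one non-centred (the whitened field is kept and re-coloured,
  scored by the binomial likelihood). The centred step mixes well when
  the data constrain the field strongly, the non-centred step when they
  do not; interweaving is robust across both regimes.

Step sizes adapt toward 44% acceptance during burn-in only, so the
retained chain is a fixed Markov kernel. The chain is seeded and
bit-reproducible. `chain_diagnostics()` reports effective sample size
(Geyer initial monotone sequence) and split-$\hat R$ per parameter —
implemented and unit-tested in-package against an analytic AR(1)
autocorrelation-time oracle — and flags parameters below a configurable
ESS floor.

The desk default is 20,000 iterations, 5,000 burn-in, thinning 15 and
1,000 prediction draws, which one CPU handles in about a minute at 100
to 150 sites. A production ("paper-fidelity") profile would raise the
iteration count to 500,000 with proportional burn-in; nothing else
changes. Whether such published iteration counts are pre- or
post-thinning is typically unstated; here `n_iterations` always counts
raw iterations and the retained-draw count is
`(n_iterations − burn_in) / thinning`.

### Prediction

For each retained draw, the latent field at all target points is drawn
from the exact joint Gaussian conditional given that draw's
hyperparameters and latent site values (one Cholesky per draw), then
mapped through the inverse logit. Prediction is **joint, not
pixelwise**: areal integrals below need the spatial dependence within
each draw. No low-rank approximation is used at desk scale (grids up to
about 5,000 pixels); larger grids should be chunked, with the
approximation documented when used. The conditional covariance carries
the nugget on its diagonal, so a predicted pixel at a surveyed location
reproduces the observation only up to micro-scale noise — intended, as
the nugget represents real fine-scale variability, not an artifact.

Numerical floors: all covariance diagonals get a jitter of
$10^{-8}\sigma^2$ (plus an absolute $10^{-12}$), and a non-positive-
definite conditional after jitter is a hard error rather than a silent
repair.

### Summaries

All percentiles in the package — pixel summary maps, areal tables,
validation quantiles — use linear interpolation between order
statistics (R's type 7). This is stated because IQR maps and IQR-based
tables are not invariant to the percentile estimator at realistic draw
counts.

## From frequency to newborns

Genotype frequencies at birth follow Hardy–Weinberg proportions
$f_{AC} = 2q(1-q)$, $f_{CC} = q^2$, with the parental allele frequency
taken equal to the mapped population frequency — the usual
HWE-at-birth assumption; no age correction is applied (differential
survival would require a demographic model, listed under limitations).
Births per pixel are population × the crude birth rate (births per
person per year) of the country containing the pixel's centre; a finer
population raster is first conservatively sum-aggregated onto the
prediction grid. Areal integrals are evaluated **per posterior draw**,
giving a full PPD of newborn counts per unit; the regional PPD is the
per-draw sum of the national PPDs on the same field draws, so per-draw
national totals add *exactly* to the regional total (a tested
identity). The regional summary could instead come from an independent
regional run; the package supports that by passing a single-unit mask,
but the shared-draw route is the default and is what the tables report.
Counts are kept unrounded internally and rounded only for presentation.

The Monte Carlo standard error attached to each reported median is the
sample standard deviation (n − 1 denominator) of the median across
repeated areal evaluations — by default 10 repeats, each re-sampling
with replacement which posterior draws enter the integral. "Sample SD
of repeated medians" is the package's fixed convention, since the
estimator behind published "Monte Carlo SE" columns is usually
unstated.

## Hold-out validation

A fraction (default 10%) of surveys is withheld uniformly at random;
the test-set size is rounded half up (445 sites at 10% → 45 test, 400
train, a tested case). The model refits on the training set and
predicts the **posterior mean frequency at the exact test coordinates**
— not the nearest pixel centre — so grid discretisation does not
contaminate the metrics. With residuals $r_i = \hat q_i - q_i$
(predicted minus observed, the fixed sign convention):

* mean error $= \bar r$ (bias),
* mean absolute error $= \overline{|r|}$ (accuracy),
* RMS error $= \sqrt{\overline{r^2}}$ (precision),

each accompanied by a dispersion value: the sample SDs of $r$, $|r|$
and $r^2$ respectively. Published metric pairs of the form
"0.012 ± 0.026" rarely define the second number; this package fixes it
as cross-site dispersion and says so. MAE ≤ RMSE always (Jensen);
no ordering between MAE and the dispersions is asserted. A single
split is the default; repeated splitting is available by calling
`holdout_split()` with different seeds.

## The synthetic-data generator

The generator exists so that every downstream stage is testable with a
known truth. It emulates the statistical structure the model assumes:

* a latent logit-scale Gaussian field with Matérn covariance over
  great-circle distance — defaults mean = logit(0.03), sill 1,
  range 500 km, nugget 0.1, matching the regime of a rare variant with
  strong spatial structure; under these defaults roughly half of the
  sampled surveys observe zero variants, emulating real databases in
  which about half the surveys report absence;
* survey sites placed uniformly over pixels (without replacement by
  default), sample sizes log-uniform between 4 and 10,000 — a desk-
  scale stand-in for the heavy-tailed sizes of real databases, whose
  documented extremes (4 to 3,212,374 individuals) the size law can be
  widened to cover; genotypes drawn multinomially under HWE so allele
  counts are exactly Binomial(2n, q);
* an optional `zero_inflation` knob forcing a fraction of surveys to
  all-AA, off by default because binomial sampling at low q already
  produces realistic zero-variant fractions;
* a clustered (log-Gaussian) population raster conserving total
  population, and a Voronoi partition into contiguous "countries" with
  crude birth rates drawn uniformly in [0.0125, 0.0477], the span of
  real African national CBRs.

What it does **not** emulate: coastlines and real country shapes,
preferential placement of surveys near settlements, covariate-driven
frequency structure, anisotropy, and reporting or georeferencing
error. Passing tests on synthetic data therefore demonstrate
correctness of the machinery under the model's own assumptions, not
robustness to the ways real survey databases violate them.

## Problem sizes used by the tests and acceptance script

Chosen as desk-scale defaults: parameter-recovery runs use 20
replicates of a 30 × 30 grid (0.5° pixels) with 100 sites and
3,000-iteration chains; the sampler-versus-quadrature oracle uses
three sites with 10,000 retained draws (thinning 3); calibration and
validation properties use 14 × 14 to 20 × 20 grids with 70–150 sites
and 2,500–5,000-iteration chains. The end-to-end smoke scenario runs a
10 × 10 grid with 40 sites and verifies bit-identical reproduction of
every output file from the same scenario seed.

## Known limitations

* Stationarity and isotropy of the field; no covariates (climate,
  malaria endemicity, settlement structure) inform the map.
* HWE at birth with the mapped frequency as the parental frequency; no
  age correction, migration adjustment, or deviation from random
  mating.
* Single-allele model: compound genotypes (SC disease,
  C/β-thalassaemia) need a multi-allelic model and are out of scope.
* Country assignment is by pixel-centre membership; border pixels are
  not split.
* The Monte Carlo SE captures only the uncertainty from which posterior
  draws enter the areal integral, not MCMC convergence error — check
  `chain_diagnostics()` before trusting the tables.
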