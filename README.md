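# hbcmap

Model-based geostatistical mapping of haemoglobin C (HbC) allele
frequency, and estimation of the annual number of affected newborns.

Haemoglobin C is a structural β-globin variant (β6Glu→Lys) common in
West Africa. Heterozygous carriers (AC) are asymptomatic and homozygotes
(CC) have mild haemolytic anaemia, but the allele matters for public
health through its compound genotypes with sickle haemoglobin and
β-thalassaemia, so carrier screening and counselling need reliable maps
of where the allele is. `hbcmap` is for epidemiologists and statistical
geneticists who want to go from scattered, heterogeneous population
surveys to a continuous allele-frequency surface with honest
uncertainty, and from there to per-country newborn burden estimates.

## The model

Surveys report genotype counts (AA/AC/CC) at georeferenced locations,
reduced to allele counts: at site *i* with 2*n*ᵢ alleles, the number of
C alleles is modelled as

> pos*ᵢ* ~ Binomial(2*n*ᵢ, logit⁻¹(μ + *f*(*s*ᵢ)))

where *f* is a stationary, isotropic Gaussian process over great-circle
distance with Matérn covariance (smoothness 3/2 by default) described by
a sill σ², a range φ (km) and a nugget τ². MCMC (elliptical slice
sampling for the latent field; interweaved centred/non-centred
random-walk updates for the covariance parameters) yields the joint
posterior, and the field is then simulated jointly at every pixel of a
prediction grid for each retained draw, giving the full posterior
predictive distribution (PPD) of the frequency map.

Genotype frequencies at birth follow Hardy–Weinberg proportions
(f_AC = 2q(1−q), f_CC = q²), and per-country newborn counts are the
birth-weighted areal integrals

> AC = Σ_pixels 2q(1−q) · pop · CBR,  CC = Σ_pixels q² · pop · CBR

evaluated **per posterior draw**, so the national and regional tables
carry medians, interquartile ranges and Monte Carlo standard errors
rather than plug-in point estimates. Hold-out validation reports the
mean error, mean absolute error and RMS error of posterior-mean
predictions at withheld sites.

A fully synthetic data generator (truth surface, heavy-tailed survey
sampling, clustered population raster, Voronoi country partition with
realistic crude birth rates) makes the entire pipeline testable end to
end without any external data.

## Worked example

```r
library(hbcmap)

grid    <- grid_spec(n_rows = 20, n_cols = 20, origin_lat = 4,
                     origin_lon = -14, cell_size = 0.75)
surface <- simulate_frequency_surface(
  grid, gp_hyperparams(mean = qlogis(0.03), sill = 1,
                       range_km = 500, nugget = 0.1), seed = 100)
surveys <- sample_surveys(surface, n_sites = 120, seed = 101)

cfg   <- mbg_config(n_iterations = 5000, burn_in = 1200, thinning = 5,
                    n_predict_samples = 400, seed = 102)
chain <- mbg_fit(surveys, cfg)
chain
#> <mbg_chain> 760 retained draws, 120 sites
#>         mean         sill     range_km       nugget
#>  -3.61574317   0.49612876 321.18542862   0.04520549

field <- predict_grid(chain, grid)
maps  <- summarize_field(field)
max(maps$median)
#> 0.0965
```

The posterior medians above are the chain's point summaries of the
logit-scale mean, sill, range (km) and nugget; the median map peaks near
10% frequency, inside the simulated truth's high-frequency zone.
Integrating over a synthetic population and five synthetic countries:

```r
pop   <- generate_population_surface(grid, total_pop = 2e7, seed = 103)
part  <- generate_country_partition(grid, k = 5, seed = 104)
demo  <- part$demographics
demo$total_pop <- sapply(demo$unit_id,
                         function(u) sum(pop$pop[part$mask$units == u]))
births <- births_surface(pop, part$mask, demo)
newborn_estimates(field, births, part$mask, demo)
#>   unit_id af_median ac_median ac_q25 ac_q75 cc_median
#> 1     C01    0.0367      5737   5496   6028     141.6
#> 2     C02    0.0371      6732   6485   7071     175.3
#> 3     C03    0.0288     25538  24116  27069     461.6
#> 4     C04    0.0446      2495   2297   2667      74.7
#> 5     C05    0.0354       869    814    929      21.0
#> 6  REGION    0.0318     41500  40048  43198     902.3

validate_model(surveys, cfg, fraction = 0.1, seed = 105)$metrics
#>   mean_error mean_absolute_error rms_error
#> 1   -0.00541              0.0256    0.0377
```

Each row gives the median and IQR of the areal PPD of newborns per year
with that genotype; the `REGION` row is computed from the per-draw sum
over units, so national draws add exactly to the regional draw. The
validation row says posterior-mean predictions at the 12 held-out sites
are nearly unbiased (ME ≈ −0.005) with a typical error of 2–3 allele
percentage points.

The same stages run from a shell via a thin wrapper:

```sh
Rscript scripts/pipeline.R all --config scenario.yaml --out out/
```

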