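Package: hbcmap
Title: Geostatistical Mapping of Haemoglobin C Allele Frequency and
    Newborn Burden
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based geostatistics for haemoglobin C (HbC): a
    binomial-likelihood Gaussian-process model maps allele frequency from
    georeferenced population surveys via Markov chain Monte Carlo, with
    joint posterior-predictive simulation on regular grids.  Posterior
    frequency fields are converted to heterozygote (AC) and homozygote
    (CC) genotype frequencies under Hardy-Weinberg equilibrium and
    integrated over population rasters and national crude birth rates to
    estimate annual affected newborns per areal unit with full posterior
    uncertainty and Monte Carlo standard errors.  Includes survey-database
    management (inclusion filtering, per-location deduplication), a
    synthetic-data generator with the statistical structure the model
    assumes, hold-out validation metrics, and a reproducible pipeline
    driven by YAML configuration with JSON run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
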