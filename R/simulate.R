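## Synthetic-data generator: ground-truth frequency surfaces, survey
## samples, population rasters and country partitions with the statistical
## structure the geostatistical model assumes.

#' Gaussian-process hyperparameters on the logit scale
#'
#' The latent allele-frequency field is modelled as a stationary Gaussian
#' process on the logit scale with a Matern covariance over great-circle
#' distance.  Defaults describe the regime the model is designed for: a
#' rare variant (mean frequency about 3%) with strong continental-scale
#' structure.
#'
#' @param mean Logit-scale mean (default `qlogis(0.03)`).
#' @param sill Process variance on the logit scale (default 1).
#' @param range_km Matern range parameter in km (default 500).
#' @param nugget Micro-scale variance on the logit scale (default 0.1).
#' @param smoothness Matern order (default 1.5).
#' @return A `gp_hyperparams` object.
#' @export
gp_hyperparams <- function(mean = stats::qlogis(0.03), sill = 1,
                           range_km = 500, nugget = 0.1, smoothness = 1.5) {
  stopifnot(sill >= 0, nugget >= 0, range_km > 0, smoothness > 0)
  structure(list(mean = mean, sill = sill, range_km = range_km,
                 nugget = nugget, smoothness = smoothness),
            class = "gp_hyperparams")
}

#' Simulate a ground-truth allele-frequency surface
#'
#' Draws one realisation of the latent logit-frequency field: a stationary
#' Gaussian process with Matern covariance over great-circle distances
#' between pixel centres, plus an independent nugget.  Frequencies are the
#' inverse logit of the latent field.
#'
#' @param grid A [grid_spec()].
#' @param params A [gp_hyperparams()].
#' @param seed Integer seed; the same seed reproduces the surface exactly.
#' @return A `true_surface`: list with `grid`, `q` (frequency matrix),
#'   `latent` (logit matrix) and `gp_params`.
#' @export
simulate_frequency_surface <- function(grid, params = gp_hyperparams(),
                                       seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "gp_hyperparams"))
  set.seed(seed)
  ctr <- pixel_centers(grid)
  n <- grid$n_pixels
  if (params$sill > 0) {
    D <- gc_distance_matrix(cbind(ctr$lat, ctr$lon))
    S <- cov_matrix(D, params$sill, params$range_km, params$smoothness,
                    params$nugget)
    U <- tryCatch(chol(S), error = function(e)
      stop("covariance matrix not positive definite after jitter; ",
           "check gp_hyperparams", call. = FALSE))
    latent <- params$mean + drop(crossprod(U, stats::rnorm(n)))
  } else {
    latent <- params$mean + stats::rnorm(n, sd = sqrt(params$nugget))
  }
  structure(list(grid = grid,
                 q = grid_matrix(stats::plogis(latent), grid),
                 latent = grid_matrix(latent, grid),
                 gp_params = params),
            class = "true_surface")
}

## heavy-tailed sample-size law: log-uniform by default
draw_sizes <- function(n, size_law) {
  if (is.function(size_law)) return(as.integer(size_law(n)))
  stopifnot(is.list(size_law))
  type <- size_law$type %||% "loguniform"
  if (type == "loguniform") {
    lo <- size_law$min %||% 4
    hi <- size_law$max %||% 10000
    stopifnot(lo >= 1, hi >= lo)
    pmax(1L, as.integer(round(exp(stats::runif(n, log(lo), log(hi))))))
  } else if (type == "fixed") {
    rep.int(as.integer(size_law$size), n)
  } else stop("unknown size_law type: ", type, call. = FALSE)
}

#' Sample synthetic surveys from a truth surface
#'
#' Sites are placed uniformly at random over grid pixels (without
#' replacement by default).  At a site with `n` individuals and pixel
#' frequency `q`, genotypes are multinomial under Hardy-Weinberg
#' proportions, so the C-allele count is exactly `Binomial(2n, q)`.
#' Sample sizes follow a heavy-tailed (log-uniform) law emulating real
#' survey databases, where sizes span orders of magnitude.
#'
#' @param surface A `true_surface` from [simulate_frequency_surface()].
#' @param n_sites Number of survey sites (>= 1).
#' @param size_law Sample-size law: a list (`list(type = "loguniform",
#'   min = 4, max = 10000)` by default, or `type = "fixed"` with `size`),
#'   or a function of `n`.
#' @param zero_inflation Probability that a survey is forced to all-AA
#'   (emulating reports of complete variant absence beyond binomial
#'   sampling); default 0.
#' @param seed Integer seed.
#' @param replace Place several sites on one pixel? Default `FALSE`.
#' @return A `survey_collection` with one row per site; the `truth`
#'   attribute records each site's pixel index and true `q`.
#' @export
sample_surveys <- function(surface, n_sites = 150,
                           size_law = list(type = "loguniform", min = 4,
                                           max = 10000),
                           zero_inflation = 0, seed = 1L, replace = FALSE) {
  stopifnot(inherits(surface, "true_surface"), n_sites >= 1,
            zero_inflation >= 0, zero_inflation <= 1)
  grid <- surface$grid
  if (!replace && n_sites > grid$n_pixels)
    stop("n_sites exceeds pixel count with replace = FALSE", call. = FALSE)
  set.seed(seed)
  pix <- sample.int(grid$n_pixels, n_sites, replace = replace)
  ctr <- pixel_centers(grid)
  n <- draw_sizes(n_sites, size_law)
  q <- as.vector(surface$q)[pix]
  geno <- vapply(seq_len(n_sites), function(i) {
    p <- c((1 - q[i])^2, 2 * q[i] * (1 - q[i]), q[i]^2)
    drop(stats::rmultinom(1L, n[i], p))
  }, numeric(3))
  forced <- stats::runif(n_sites) < zero_inflation
  geno[, forced] <- rbind(n[forced], 0, 0)
  df <- tibble::tibble(
    source_id = sprintf("SYN-%04d", seq_len(n_sites)),
    latitude = ctr$lat[pix], longitude = ctr$lon[pix],
    year = sample(1950:2010, n_sites, replace = TRUE),
    n_individuals = n,
    n_AA = geno[1, ], n_AC = geno[2, ], n_CC = geno[3, ],
    diagnostic_method = sample(c("molecular", "HPLC", "electrophoresis"),
                               n_sites, replace = TRUE),
    representative = TRUE)
  out <- as_survey_collection(df, provenance = sprintf(
    "synthetic surveys (seed %d, %d sites)", seed, n_sites))
  attr(out, "truth") <- tibble::tibble(pixel = pix, true_q = q)
  out
}

#' Generate a clustered synthetic population raster
#'
#' Per-pixel population counts with a log-Gaussian spatial pattern:
#' `pop = total_pop * exp(clustering * Z) / sum(exp(clustering * Z))`
#' where `Z` is a unit-variance Gaussian-process draw.  `clustering = 0`
#' gives a uniform population.
#'
#' @param grid A [grid_spec()].
#' @param total_pop Total population over the grid (> 0).
#' @param clustering Log-scale clustering strength (>= 0); default 1.
#' @param range_km Spatial range of the clustering pattern (km).
#' @param seed Integer seed.
#' @return A `population_surface`: list with `grid` and `pop` matrix whose
#'   values are non-negative and sum to `total_pop`.
#' @export
generate_population_surface <- function(grid, total_pop = 2e7, clustering = 1,
                                        range_km = 300, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), total_pop > 0, clustering >= 0)
  if (clustering > 0) {
    z <- simulate_frequency_surface(
      grid, gp_hyperparams(mean = 0, sill = 1, range_km = range_km,
                           nugget = 0), seed = seed)$latent
    w <- exp(clustering * as.vector(z))
  } else {
    w <- rep.int(1, grid$n_pixels)
  }
  pop <- total_pop * w / sum(w)
  structure(list(grid = grid, pop = grid_matrix(pop, grid)),
            class = "population_surface")
}

#' Partition a grid into synthetic countries with crude birth rates
#'
#' Pixels are assigned to the nearest of `k` seed pixels by great-circle
#' distance (Voronoi growth), giving `k` contiguous regions covering the
#' grid exactly once.  Each region receives a crude birth rate drawn
#' uniformly within the span observed across African national statistics
#' (0.0125 to 0.0477 births per person per year).
#'
#' @param grid A [grid_spec()].
#' @param k Number of regions, `1 <= k <= n_pixels`.
#' @param seed Integer seed.
#' @return A list with `mask` (a `country_mask`: `grid` plus a matrix of
#'   unit labels) and `demographics` (tibble: `unit_id`, `cbr`,
#'   `total_pop`, the latter `NA` until populated).
#' @export
generate_country_partition <- function(grid, k = 5, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), k >= 1, k <= grid$n_pixels)
  set.seed(seed)
  ctr <- pixel_centers(grid)
  seeds <- sample.int(grid$n_pixels, k)
  D <- gc_distance_matrix(cbind(ctr$lat, ctr$lon),
                          cbind(ctr$lat[seeds], ctr$lon[seeds]))
  assign <- max.col(-D, ties.method = "first")
  ids <- sprintf("C%02d", seq_len(k))
  mask <- structure(list(grid = grid,
                         units = grid_matrix(ids[assign], grid)),
                    class = "country_mask")
  demo <- tibble::tibble(unit_id = ids,
                         cbr = stats::runif(k, 0.0125, 0.0477),
                         total_pop = NA_real_)
  list(mask = mask, demographics = demo)
}
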