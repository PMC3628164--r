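## Shared fixture builders: small, fast synthetic setups used across the
## suite.  Everything is generated in code under fixed seeds.

tiny_grid <- function(n = 10, cell = 0.5) {
  grid_spec(n, n, origin_lat = 6, origin_lon = -8, cell_size = cell)
}

quick_config <- function(...) {
  mbg_config(n_iterations = 1500, burn_in = 400, thinning = 5,
             n_predict_samples = 150, seed = 42L, ...)
}

## a small survey data frame with valid rows
survey_df <- function() {
  data.frame(
    source_id = c("S1", "S2", "S3"),
    latitude = c(12.0, 10.5, 8.25),
    longitude = c(-1.5, 0.25, -3.0),
    year = c(1990, 1975, 2005),
    n_individuals = c(100, 250, 40),
    n_AA = c(90, 245, 40),
    n_AC = c(9, 5, 0),
    n_CC = c(1, 0, 0),
    diagnostic_method = c("electrophoresis", "HPLC", "molecular"),
    representative = TRUE,
    stringsAsFactors = FALSE)
}

## small synthetic world reused by demography tests
demo_world <- function(seed = 11L) {
  g <- tiny_grid(8)
  surface <- simulate_frequency_surface(g, gp_hyperparams(), seed = seed)
  pop <- generate_population_surface(g, total_pop = 1e6, clustering = 1,
                                     seed = seed + 1L)
  part <- generate_country_partition(g, k = 3, seed = seed + 2L)
  demo <- part$demographics
  demo$total_pop <- vapply(demo$unit_id, function(u)
    sum(pop$pop[part$mask$units == u]), 0)
  list(grid = g, surface = surface, pop = pop, mask = part$mask,
       demo = demo)
}

## deterministic posterior-field stand-in: draws supplied explicitly
field_from_draws <- function(draws, grid) {
  structure(list(samples = draws,
                 coords = pixel_centers(grid)[, c("lat", "lon")],
                 grid = grid, provenance = "fixture"),
            class = "posterior_field_samples")
}

tiny_scenario <- function(seed = 1L) {
  sc <- default_scenario(seed)
  sc$grid <- list(n_rows = 10, n_cols = 10, origin_lat = 6,
                  origin_lon = -8, cell_size = 0.5)
  sc$surveys$n_sites <- 40
  sc$partition$k <- 3
  sc$model <- list(n_iterations = 1200, burn_in = 300, thinning = 5,
                   n_predict_samples = 120, smoothness = 1.5,
                   jitter = 1e-8)
  sc$estimate$n_repeats <- 4
  sc
}
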