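test_that("Hardy-Weinberg genotype frequencies follow the closed form", {
  expect_equal(hwe_genotype_freqs(0),
               tibble::tibble(f_AA = 1, f_AC = 0, f_CC = 0))
  expect_equal(hwe_genotype_freqs(0.5),
               tibble::tibble(f_AA = 0.25, f_AC = 0.5, f_CC = 0.25))
  f <- hwe_genotype_freqs(0.13)
  expect_equal(f$f_AC, 0.2262)
  expect_equal(f$f_CC, 0.0169)
  expect_error(hwe_genotype_freqs(1.2), "\\[0, 1\\]")
})

test_that("genotype frequencies sum to one and behave monotonically", {
  q <- seq(0, 1, by = 0.01)
  f <- hwe_genotype_freqs(q)
  expect_true(all(abs(f$f_AA + f$f_AC + f$f_CC - 1) < 1e-12))
  ## heterozygosity peaks at q = 0.5 with value 0.5
  expect_equal(max(f$f_AC), 0.5)
  expect_equal(q[which.max(f$f_AC)], 0.5)
  ## homozygote frequency strictly increasing
  expect_true(all(diff(f$f_CC) > 0))
})

test_that("births are population times the unit birth rate", {
  g <- grid_spec(1, 1, origin_lat = 0, origin_lon = 0, cell_size = 1)
  pop <- structure(list(grid = g, pop = matrix(1000, 1, 1)),
                   class = "population_surface")
  mask <- structure(list(grid = g, units = matrix("A", 1, 1)),
                    class = "country_mask")
  demo <- tibble::tibble(unit_id = "A", cbr = 0.04, total_pop = 1000)
  expect_equal(births_surface(pop, mask, demo), matrix(40, 1, 1))
  demo0 <- tibble::tibble(unit_id = "A", cbr = 0, total_pop = 1000)
  expect_equal(births_surface(pop, mask, demo0), matrix(0, 1, 1))
  expect_error(births_surface(pop, mask,
                              tibble::tibble(unit_id = "B", cbr = 0.04)),
               "A")
})

test_that("finer population rasters are sum-aggregated onto the mask grid", {
  g <- grid_spec(1, 1, origin_lat = 0, origin_lon = 0, cell_size = 1)
  fine <- grid_spec(2, 2, origin_lat = 0, origin_lon = 0, cell_size = 0.5)
  pop <- structure(list(grid = fine, pop = matrix(1:4, 2, 2)),
                   class = "population_surface")
  mask <- structure(list(grid = g, units = matrix("A", 1, 1)),
                    class = "country_mask")
  demo <- tibble::tibble(unit_id = "A", cbr = 0.1)
  expect_equal(births_surface(pop, mask, demo), matrix(1, 1, 1))  # 10 * 0.1
})

test_that("the areal integral matches the single-pixel closed form", {
  g <- grid_spec(1, 1, origin_lat = 0, origin_lon = 0, cell_size = 1)
  field <- field_from_draws(matrix(0.1, nrow = 50, ncol = 1), g)
  mask <- structure(list(grid = g, units = matrix("A", 1, 1)),
                    class = "country_mask")
  births <- matrix(40, 1, 1)
  ppd <- areal_newborn_ppd(field, births, mask, "A")
  expect_equal(ppd$ac, rep(2 * 0.1 * 0.9 * 40, 50))  # 7.2
  expect_equal(ppd$cc, rep(0.01 * 40, 50))           # 0.4
  zero <- areal_newborn_ppd(field_from_draws(matrix(0, 50, 1), g),
                            births, mask, "A")
  expect_true(all(zero$ac == 0) && all(zero$cc == 0))
  expect_error(areal_newborn_ppd(field, births, mask, "Z"), "no pixels")
})

test_that("per-draw areal integrals are additive over sub-units", {
  w <- demo_world()
  draws <- matrix(runif(60 * w$grid$n_pixels, 0, 0.3), nrow = 60)
  field <- field_from_draws(draws, w$grid)
  births <- births_surface(w$pop, w$mask, w$demo)
  per_unit <- lapply(w$demo$unit_id, function(u)
    areal_newborn_ppd(field, births, w$mask, u))
  whole <- structure(list(grid = w$grid,
                          units = matrix("ALL", w$grid$n_rows,
                                         w$grid$n_cols)),
                     class = "country_mask")
  all_ppd <- areal_newborn_ppd(field, births, whole, "ALL")
  expect_equal(Reduce(`+`, lapply(per_unit, `[[`, "ac")), all_ppd$ac)
  expect_equal(Reduce(`+`, lapply(per_unit, `[[`, "cc")), all_ppd$cc)
  ## never negative, never more than the unit's total births
  for (i in seq_along(per_unit)) {
    b_tot <- sum(births[w$mask$units == w$demo$unit_id[i]])
    expect_true(all(per_unit[[i]]$ac >= 0 & per_unit[[i]]$ac <= b_tot))
    expect_true(all(per_unit[[i]]$cc >= 0 & per_unit[[i]]$cc <= b_tot))
  }
})

test_that("the estimate table is coherent and scales linearly with population", {
  w <- demo_world()
  set.seed(30)
  draws <- matrix(runif(80 * w$grid$n_pixels, 0, 0.3), nrow = 80)
  field <- field_from_draws(draws, w$grid)
  births <- births_surface(w$pop, w$mask, w$demo)
  tab <- newborn_estimates(field, births, w$mask, w$demo)
  expect_true(all(tab$ac_q25 <= tab$ac_median & tab$ac_median <= tab$ac_q75))
  expect_true(all(tab$cc_q25 <= tab$cc_median & tab$cc_median <= tab$cc_q75))
  expect_true("REGION" %in% tab$unit_id)

  ## regional per-draw total is the sum of national per-draw totals, so
  ## every quantile doubles when the population doubles
  pop2 <- w$pop
  pop2$pop <- 2 * pop2$pop
  tab2 <- newborn_estimates(field, births_surface(pop2, w$mask, w$demo),
                            w$mask, w$demo)
  num <- vapply(tab, is.numeric, TRUE) &
    !names(tab) %in% c("total_pop", "cbr", "af_median", "af_q25", "af_q75")
  expect_equal(as.matrix(tab2[, num]), 2 * as.matrix(tab[, num]))

  ## regional summaries come from the per-draw sum across units
  ppds <- attr(tab, "ppds")
  reg <- Reduce(`+`, lapply(ppds, `[[`, "ac"))
  expect_equal(tab$ac_median[tab$unit_id == "REGION"],
               unname(quantile(reg, 0.5, type = 7)))
})

test_that("Monte Carlo standard errors are sample SDs over repeats", {
  fn <- function(s) c(x = c(10, 12, 14)[s])
  expect_equal(monte_carlo_se(fn, n_repeats = 3), c(x = 2))
  expect_equal(monte_carlo_se(function(s) c(y = 5), n_repeats = 4),
               c(y = 0))
  expect_error(monte_carlo_se(fn, n_repeats = 1), "at least 2")

  ## resampled medians vary a little but hover near the full-draw medians
  w <- demo_world()
  set.seed(31)
  draws <- matrix(runif(100 * w$grid$n_pixels, 0, 0.2), nrow = 100)
  field <- field_from_draws(draws, w$grid)
  births <- births_surface(w$pop, w$mask, w$demo)
  se <- monte_carlo_se(function(s)
    resampled_medians(field, births, w$mask, w$demo, s),
    n_repeats = 5)
  expect_true(all(is.finite(se)) && all(se >= 0))
})
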