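test_that("great-circle distances behave like a metric on the sphere", {
  expect_equal(great_circle_km(c(10, 20), c(10, 20)), 0)
  ## quarter great circle, closed form pi * R / 2
  expect_equal(great_circle_km(c(0, 0), c(0, 90)),
               pi * earth_radius_km() / 2, tolerance = 1e-6)
  set.seed(1)
  for (i in 1:10) {
    a <- c(runif(1, -80, 80), runif(1, -170, 170))
    b <- c(runif(1, -80, 80), runif(1, -170, 170))
    expect_equal(great_circle_km(a, b), great_circle_km(b, a))
  }
  D <- gc_distance_matrix(cbind(c(0, 10, -5), c(0, 10, 20)))
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
})

test_that("the Matern covariance has its closed-form values and is PSD", {
  expect_equal(matern_cov(0, sill = 1.3, range_km = 500, nugget = 0.2), 1.5)
  ## exponential special case at one range
  expect_equal(matern_cov(500, sill = 2, range_km = 500, smoothness = 0.5),
               2 * exp(-1))
  ## strictly decreasing, vanishing far away
  d <- seq(0, 5000, by = 250)
  v <- matern_cov(d, 1, 500, 1.5, 0)
  expect_true(all(diff(v) < 0))
  expect_lt(v[length(v)], 1e-4)
  expect_error(matern_cov(-1, 1, 500), "negative")
  set.seed(2)
  pts <- cbind(runif(10, -10, 10), runif(10, -10, 10))
  S <- matern_cov(gc_distance_matrix(pts), 1, 300, 1.5, 0)
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  ## general-smoothness branch agrees with the nu = 3/2 closed form
  expect_equal(matern_cov(c(0, 100, 700), 1, 400, 1.5, 0),
               hbcmap:::matern_corr(c(0, 100, 700), 400, 1.5 + 1e-12),
               tolerance = 1e-6)
})

test_that("a single-site fit matches the quadrature posterior under a matched prior", {
  sv <- as_survey_collection(data.frame(
    source_id = "S", latitude = 5, longitude = 5, year = 2000,
    n_individuals = 50, n_AA = 25, n_AC = 0, n_CC = 25,
    diagnostic_method = "molecular", representative = TRUE))
  expect_equal(sv$pos, 50)
  cfg <- mbg_config(n_iterations = 6000, burn_in = 1000, thinning = 1,
                    n_predict_samples = 100, seed = 3,
                    fixed = list(mean = 0, sill = 0, nugget = 1))
  ch <- mbg_fit(sv, cfg)
  freq <- plogis(ch$latent[, 1])
  ## brute-force quadrature with the same N(0, 1) prior on the logit
  z <- seq(-8, 8, length.out = 4001)
  w <- dbinom(50, 100, plogis(z)) * dnorm(z, 0, 1)
  oracle_mean <- sum(plogis(z) * w) / sum(w)
  mc_se <- sd(freq) / sqrt(hbcmap::effective_sample_size(freq))
  expect_lt(abs(mean(freq) - oracle_mean), 4 * mc_se + 0.002)
})

test_that("uniformly zero-variant data shrink the frequency below the prior", {
  df <- survey_df()[rep(1, 5), ]
  df$latitude <- df$latitude + 0:4
  df$n_individuals <- 2000
  df$n_AA <- 2000; df$n_AC <- 0; df$n_CC <- 0
  sv <- as_survey_collection(df)
  mu0 <- qlogis(0.05)
  cfg <- mbg_config(n_iterations = 3000, burn_in = 500, thinning = 1,
                    n_predict_samples = 100, seed = 4,
                    fixed = list(mean = mu0, sill = 0, nugget = 1))
  ch <- mbg_fit(sv, cfg)
  prior_q975 <- plogis(qnorm(0.975, mu0, 1))
  post_q975 <- quantile(plogis(ch$latent), 0.975, names = FALSE)
  expect_lt(post_q975, prior_q975)
  expect_lt(median(plogis(ch$latent)), 0.01)
})

test_that("fitting is reproducible and rejects degenerate inputs", {
  g <- tiny_grid(6)
  s <- simulate_frequency_surface(g, gp_hyperparams(), seed = 2)
  sv <- sample_surveys(s, n_sites = 15, seed = 3)
  cfg <- mbg_config(n_iterations = 600, burn_in = 100, thinning = 5,
                    n_predict_samples = 10, seed = 5)
  ch1 <- mbg_fit(sv, cfg)
  ch2 <- mbg_fit(sv, cfg)
  expect_identical(ch1$draws, ch2$draws)
  expect_identical(ch1$latent, ch2$latent)

  same <- sv
  same$latitude <- rep(sv$latitude[1], nrow(sv))
  same$longitude <- rep(sv$longitude[1], nrow(sv))
  expect_error(mbg_fit(same, cfg), "identical|one location")
})

test_that("prediction reproduces a heavily sampled site and reverts to the prior far away", {
  df <- survey_df()[rep(1, 4), ]
  df$latitude <- c(8, 8, 9, 9)
  df$longitude <- c(-3, -2, -3, -2)
  df$n_individuals <- c(50000, 4000, 4000, 4000)
  df$n_CC <- 0
  df$n_AC <- round(2 * df$n_individuals * 0.10)
  df$n_AA <- df$n_individuals - df$n_AC
  sv <- as_survey_collection(df)
  cfg <- mbg_config(n_iterations = 4000, burn_in = 1000, thinning = 3,
                    n_predict_samples = 1000, seed = 6,
                    fixed = list(mean = qlogis(0.05), sill = 0.5,
                                 range_km = 300, nugget = 0.005))
  ch <- mbg_fit(sv, cfg)
  ## pixel at the n = 50,000 site: the data dominate
  at_site <- predict_points(ch, 8, -3, n_samples = 1000)
  expect_lt(abs(median(at_site$samples) - 0.10), 0.02)

  ## pixel >> 10 range away: PPD ~ prior predictive plogis(N(mu, s + g))
  far <- predict_points(ch, 8, 80, n_samples = 1000)
  qgrid <- seq(0.001, 0.999, by = 0.002)
  theo_cdf <- pnorm(qlogis(qgrid), qlogis(0.05), sqrt(0.5 + 0.005))
  emp_cdf <- ecdf(far$samples)(qgrid)
  expect_lt(max(abs(emp_cdf - theo_cdf)), 0.06)
})

test_that("a pixel between two symmetric equal sites has a symmetric PPD", {
  mk <- function(flip) {
    df <- survey_df()[c(1, 1), ]
    df$latitude <- c(7, 9)
    if (flip) df$latitude <- rev(df$latitude)
    df$longitude <- -3
    df$n_individuals <- 3000
    df$n_CC <- 0
    df$n_AC <- 300
    df$n_AA <- df$n_individuals - df$n_AC
    as_survey_collection(df)
  }
  cfg <- mbg_config(n_iterations = 2000, burn_in = 500, thinning = 3,
                    n_predict_samples = 500, seed = 7,
                    fixed = list(mean = qlogis(0.05), sill = 0.5,
                                 range_km = 300, nugget = 0.01))
  p1 <- predict_points(mbg_fit(mk(FALSE), cfg), 8, -3, n_samples = 500)
  p2 <- predict_points(mbg_fit(mk(TRUE), cfg), 8, -3, n_samples = 500)
  expect_lt(abs(median(p1$samples) - median(p2$samples)), 0.01)
})

test_that("field summaries use type-7 percentiles and keep their ordering", {
  g <- grid_spec(1, 2, origin_lat = 0, origin_lon = 0, cell_size = 1)
  draws <- cbind(rep(0.3, 100), (1:100) / 100)
  f <- field_from_draws(draws, g)
  m <- summarize_field(f)
  expect_equal(m$mean[1, 1], 0.3)
  expect_equal(m$median[1, 1], 0.3)
  expect_equal(m$iqr_width[1, 1], 0)
  expect_equal(m$q25[1, 2], 0.2575)
  expect_equal(m$q75[1, 2], 0.7525)
  expect_true(all(m$q25 <= m$median & m$median <= m$q75))
  expect_true(all(m$mean >= 0 & m$mean <= 1))
  expect_error(summarize_field(field_from_draws(draws[1, , drop = FALSE], g)),
               "at least 2")
})

test_that("diagnostics separate white-noise, autocorrelated and constant chains", {
  set.seed(8)
  iid <- rnorm(2000)
  expect_lt(abs(split_rhat(iid) - 1), 0.02)
  expect_gt(effective_sample_size(iid), 1000)

  ## AR(1) with rho = 0.95: analytic ESS = n (1 - rho) / (1 + rho)
  rho <- 0.95
  n <- 20000
  x <- as.vector(arima.sim(list(ar = rho), n))
  e <- effective_sample_size(x)
  analytic <- n * (1 - rho) / (1 + rho)
  expect_lt(e, n / 10)
  expect_gt(e, analytic / 3)
  expect_lt(e, analytic * 3)

  expect_true(is.na(effective_sample_size(rep(1, 100))))

  ch <- list(draws = tibble::tibble(mean = rnorm(500), sill = rep(2, 500),
                                    range_km = runif(500), nugget = rnorm(500)),
             acceptance = c(mean = 0.4), config = NULL)
  class(ch) <- "mbg_chain"
  d <- chain_diagnostics(ch, ess_floor = 10)
  expect_true(d$flagged[d$parameter == "sill"])   # degenerate chain
  expect_false(d$flagged[d$parameter == "mean"])
})

test_that("50% prediction intervals cover the truth at about half of held-out pixels", {
  g <- grid_spec(14, 14, origin_lat = 4, origin_lon = -10, cell_size = 0.7)
  s <- simulate_frequency_surface(
    g, gp_hyperparams(mean = qlogis(0.05), sill = 1, range_km = 400,
                      nugget = 0.05), seed = 21)
  sv <- sample_surveys(s, n_sites = 70,
                       size_law = list(type = "loguniform", min = 50,
                                       max = 5000), seed = 22)
  cfg <- mbg_config(n_iterations = 3000, burn_in = 800, thinning = 5,
                    n_predict_samples = 400, seed = 23)
  ch <- mbg_fit(sv, cfg)
  held_out <- setdiff(seq_len(g$n_pixels), attr(sv, "truth")$pixel)
  field <- predict_grid(ch, g, n_samples = 400)
  maps <- summarize_field(field)
  truth <- as.vector(s$q)[held_out]
  cover <- mean(truth >= as.vector(maps$q25)[held_out] &
                  truth <= as.vector(maps$q75)[held_out])
  expect_gt(cover, 0.35)
  expect_lt(cover, 0.65)
})

test_that("more individuals at a site never widen its posterior IQR", {
  mk <- function(n_big) {
    df <- survey_df()[rep(1, 5), ]
    df$latitude <- c(8, 6, 10, 8, 8)
    df$longitude <- c(-3, -3, -3, -5, -1)
    df$n_individuals <- c(n_big, 500, 500, 500, 500)
    df$n_CC <- 0
    df$n_AC <- round(2 * df$n_individuals * 0.05)
    df$n_AA <- df$n_individuals - df$n_AC
    as_survey_collection(df)
  }
  cfg <- mbg_config(n_iterations = 3000, burn_in = 600, thinning = 3,
                    n_predict_samples = 800, seed = 9,
                    fixed = list(mean = qlogis(0.05), sill = 0.5,
                                 range_km = 300, nugget = 0.02))
  iqr_at_site <- function(n_big) {
    p <- predict_points(mbg_fit(mk(n_big), cfg), 8, -3, n_samples = 800)
    diff(quantile(p$samples, c(0.25, 0.75), names = FALSE))
  }
  small_n <- iqr_at_site(50)
  big_n <- iqr_at_site(20000)
  expect_lt(big_n, small_n + 0.005)
})
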