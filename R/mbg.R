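## Bayesian model-based geostatistics for allele counts:
##   pos_i ~ Binomial(pos_i + neg_i, plogis(mu + f_i))
##   f ~ GP(0, sill * Matern_nu(d; range) + nugget * I) over great-circle km
## MCMC: elliptical slice sampling for f; random-walk Metropolis for mu;
## interweaved centred / non-centred (whitened) random-walk updates for
## sill, range and nugget, which mixes robustly whether the binomial data
## are strong or weak relative to the field prior.

#' Model configuration for geostatistical inference
#'
#' Defaults are a desk-scale profile (20,000 iterations); a "paper
#' fidelity" profile for production runs would raise `n_iterations` to
#' 500,000 with proportional burn-in and thinning.
#'
#' @param n_iterations Total MCMC iterations (> `burn_in`).
#' @param burn_in Iterations discarded (>= 0); step sizes adapt only here.
#' @param thinning Keep every `thinning`-th post-burn-in iteration (>= 1).
#' @param n_predict_samples Posterior draws used for field prediction
#'   (>= 2).
#' @param smoothness Matern order of the spatial covariance (default 3/2).
#' @param priors List of prior settings: `mean_mu`, `mean_sd` (normal
#'   prior on the logit-scale mean), `sill_rate`, `nugget_rate`
#'   (exponential rates) and `range_mean` (exponential mean, km).
#' @param fixed Named list of hyperparameters held fixed instead of
#'   sampled, e.g. `list(sill = 0)` disables spatial correlation.
#' @param jitter Relative diagonal stabiliser added to covariance
#'   matrices (default 1e-8, scaled by the sill).
#' @param seed Integer seed for the sampler.
#' @return An `mbg_config` object.
#' @export
mbg_config <- function(n_iterations = 20000, burn_in = 5000, thinning = 15,
                       n_predict_samples = 1000, smoothness = 1.5,
                       priors = list(), fixed = list(), jitter = 1e-8,
                       seed = 1L) {
  stopifnot(n_iterations > burn_in, burn_in >= 0, thinning >= 1,
            n_predict_samples >= 2, smoothness > 0, jitter >= 0)
  defaults <- list(mean_mu = stats::qlogis(0.01), mean_sd = 2,
                   sill_rate = 1, range_mean = 500, nugget_rate = 10)
  priors <- utils::modifyList(defaults, priors)
  bad <- setdiff(names(fixed), c("mean", "sill", "range_km", "nugget"))
  if (length(bad))
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 n_predict_samples = as.integer(n_predict_samples),
                 smoothness = smoothness, priors = priors, fixed = fixed,
                 jitter = jitter, seed = as.integer(seed)),
            class = "mbg_config")
}

## log prior densities for the sampled hyperparameters
hyper_logprior <- function(par, value, priors) {
  switch(par,
         mean = stats::dnorm(value, priors$mean_mu, priors$mean_sd, log = TRUE),
         sill = stats::dexp(value, priors$sill_rate, log = TRUE),
         range_km = stats::dexp(value, 1 / priors$range_mean, log = TRUE),
         nugget = stats::dexp(value, priors$nugget_rate, log = TRUE))
}

## one elliptical slice sampling update of the zero-mean latent vector
ess_update <- function(f, U, loglik) {
  nu <- drop(crossprod(U, stats::rnorm(length(f))))
  logy <- loglik(f) + log(stats::runif(1))
  theta <- stats::runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi
  hi <- theta
  repeat {
    fp <- f * cos(theta) + nu * sin(theta)
    if (loglik(fp) > logy) return(fp)
    if (theta < 0) lo <- theta else hi <- theta
    theta <- stats::runif(1, lo, hi)
  }
}

#' Fit the geostatistical allele-frequency model by MCMC
#'
#' Samples the posterior of the logit-scale mean, sill, range, nugget and
#' the latent logit frequencies at the survey locations, under a binomial
#' likelihood for the C-allele counts and a Gaussian-process prior over
#' great-circle distance.
#'
#' @param surveys A `survey_collection` (needs `latitude`, `longitude`,
#'   `pos`, `neg`).
#' @param config An [mbg_config()].
#' @return An `mbg_chain`: `draws` (tibble of retained hyperparameter
#'   draws), `latent` (matrix of retained logit draws at data sites),
#'   `acceptance` (per-block rates), `data`, `D` (site distance matrix,
#'   km), and the `config`.
#' @export
mbg_fit <- function(surveys, config = mbg_config()) {
  stopifnot(inherits(config, "mbg_config"))
  pos <- surveys$pos
  N <- surveys$pos + surveys$neg
  if (length(pos) < 1L) stop("no surveys to fit", call. = FALSE)
  if (any(!is.finite(pos)) || any(pos < 0) || any(pos > N))
    stop("invalid allele counts", call. = FALSE)
  coords <- cbind(surveys$latitude, surveys$longitude)
  n <- length(pos)
  D <- gc_distance_matrix(coords)
  fx <- config$fixed
  if (n > 1L && all(D[upper.tri(D)] < 1e-9) && is.null(fx$sill))
    stop("all surveys share one location; spatial model unidentifiable",
         call. = FALSE)
  pri <- config$priors
  set.seed(config$seed)

  ## state, initialised at prior centres (or fixed values)
  mu <- fx$mean %||% pri$mean_mu
  sill <- fx$sill %||% (1 / pri$sill_rate)
  range_km <- fx$range_km %||% pri$range_mean
  nugget <- fx$nugget %||% (1 / pri$nugget_rate)
  f <- rep.int(0, n)

  make_chol <- function(s, r, g) {
    S <- cov_matrix(D, s, r, config$smoothness, g, config$jitter)
    tryCatch(chol(S), error = function(e)
      stop("covariance matrix singular after jitter", call. = FALSE))
  }
  U <- make_chol(sill, range_km, nugget)

  binom_ll <- function(f, mu) sum(stats::dbinom(pos, N, stats::plogis(mu + f),
                                                log = TRUE))
  gp_ll <- function(f, U) {
    w <- backsolve(U, f, transpose = TRUE)
    -sum(log(diag(U))) - 0.5 * sum(w * w)
  }

  sampled <- c(if (is.null(fx$mean)) c("mean", "mean_shift"),
               if (is.null(fx$sill)) "sill",
               if ((is.null(fx$sill) || fx$sill > 0) &&
                   is.null(fx$range_km)) "range_km",
               if (is.null(fx$nugget)) "nugget")
  steps <- stats::setNames(rep.int(0.4, length(sampled)), sampled)
  acc <- stats::setNames(rep.int(0, length(sampled)), sampled)
  tries <- acc

  n_keep <- (config$n_iterations - config$burn_in) %/% config$thinning
  draws <- matrix(NA_real_, n_keep, 4,
                  dimnames = list(NULL, c("mean", "sill", "range_km", "nugget")))
  latent <- matrix(NA_real_, n_keep, n)
  kept <- 0L

  spatial_on <- is.null(fx$sill) || fx$sill > 0

  for (it in seq_len(config$n_iterations)) {
    ## latent field
    f <- ess_update(f, U, function(g) binom_ll(g, mu))

    ## logit-scale mean: random-walk Metropolis on the binomial likelihood
    if ("mean" %in% sampled) {
      prop <- mu + stats::rnorm(1, sd = exp(steps[["mean"]]))
      lr <- binom_ll(f, prop) - binom_ll(f, mu) +
        hyper_logprior("mean", prop, pri) - hyper_logprior("mean", mu, pri)
      tries[["mean"]] <- tries[["mean"]] + 1
      if (log(stats::runif(1)) < lr) {
        mu <- prop
        acc[["mean"]] <- acc[["mean"]] + 1
      }
      ## likelihood-invariant translation: shift mu and counter-shift f,
      ## scored by the field prior; decouples mu from the latent field
      delta <- stats::rnorm(1, sd = exp(steps[["mean_shift"]]))
      f2 <- f - delta
      lr <- gp_ll(f2, U) - gp_ll(f, U) +
        hyper_logprior("mean", mu + delta, pri) -
        hyper_logprior("mean", mu, pri)
      tries[["mean_shift"]] <- tries[["mean_shift"]] + 1
      if (log(stats::runif(1)) < lr) {
        mu <- mu + delta
        f <- f2
        acc[["mean_shift"]] <- acc[["mean_shift"]] + 1
      }
    }

    ## covariance hyperparameters: centred then whitened update each
    for (par in intersect(c("sill", "range_km", "nugget"), sampled)) {
      cur <- switch(par, sill = sill, range_km = range_km, nugget = nugget)
      ## (a) centred: proposal scored by the GP density of f
      prop <- cur * exp(stats::rnorm(1, sd = exp(steps[[par]])))
      s2 <- if (par == "sill") prop else sill
      r2 <- if (par == "range_km") prop else range_km
      g2 <- if (par == "nugget") prop else nugget
      U2 <- make_chol(s2, r2, g2)
      lr <- gp_ll(f, U2) - gp_ll(f, U) +
        hyper_logprior(par, prop, pri) - hyper_logprior(par, cur, pri) +
        log(prop) - log(cur)
      tries[[par]] <- tries[[par]] + 0.5
      if (log(stats::runif(1)) < lr) {
        sill <- s2; range_km <- r2; nugget <- g2; U <- U2
        cur <- prop
        acc[[par]] <- acc[[par]] + 0.5
      }
      ## (b) non-centred: whiten f, move the parameter, re-colour;
      ##     scored by the binomial likelihood of the re-coloured field
      v <- backsolve(U, f, transpose = TRUE)
      prop <- cur * exp(stats::rnorm(1, sd = exp(steps[[par]])))
      s2 <- if (par == "sill") prop else sill
      r2 <- if (par == "range_km") prop else range_km
      g2 <- if (par == "nugget") prop else nugget
      U2 <- make_chol(s2, r2, g2)
      f2 <- drop(crossprod(U2, v))
      lr <- binom_ll(f2, mu) - binom_ll(f, mu) +
        hyper_logprior(par, prop, pri) - hyper_logprior(par, cur, pri) +
        log(prop) - log(cur)
      tries[[par]] <- tries[[par]] + 0.5
      if (log(stats::runif(1)) < lr) {
        sill <- s2; range_km <- r2; nugget <- g2; U <- U2; f <- f2
        acc[[par]] <- acc[[par]] + 0.5
      }
    }

    ## step-size adaptation during burn-in only
    if (it <= config$burn_in && it %% 50 == 0) {
      for (par in sampled) {
        rate <- if (tries[[par]] > 0) acc[[par]] / tries[[par]] else 0.44
        steps[[par]] <- steps[[par]] + (rate - 0.44) / sqrt(it / 50)
      }
      acc[] <- 0
      tries[] <- 0
    }

    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thinning == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(mu, sill, range_km, nugget)
      latent[kept, ] <- mu + f
    }
  }

  if (any(!is.finite(draws)))
    stop("MCMC chain contains non-finite values", call. = FALSE)
  rates <- ifelse(tries > 0, acc / tries, NA_real_)
  structure(list(draws = tibble::as_tibble(as.data.frame(draws)),
                 latent = latent,
                 acceptance = rates,
                 data = list(latitude = surveys$latitude,
                             longitude = surveys$longitude,
                             pos = pos, N = N),
                 D = D,
                 spatial = spatial_on,
                 config = config),
            class = "mbg_chain")
}

#' @export
print.mbg_chain <- function(x, ...) {
  cat(sprintf("<mbg_chain> %d retained draws, %d sites\n",
              nrow(x$draws), length(x$data$pos)))
  print(vapply(x$draws, stats::median, numeric(1)))
  invisible(x)
}

## evenly recycle retained draw indices up to n_samples
draw_indices <- function(n_draws, n_samples) {
  ((seq_len(n_samples) - 1L) %% n_draws) + 1L
}

#' Posterior-predictive frequency samples at arbitrary points
#'
#' For each retained posterior draw the latent field at the target points
#' is simulated jointly from the Gaussian-process conditional given that
#' draw's hyperparameters and latent values at the data sites (exact
#' conditional simulation, not pixelwise-independent), then mapped through
#' the inverse logit.
#'
#' @param chain An `mbg_chain` from [mbg_fit()].
#' @param lat,lon Coordinates of the target points (degrees).
#' @param n_samples Number of posterior draws (default from the config).
#' @param seed Seed for the conditional simulation.
#' @return A `posterior_field_samples`: `samples` (`n_samples x n_points`
#'   matrix of frequencies in [0, 1]), `coords`, `grid` (`NULL` here) and
#'   the config hash as `provenance`.
#' @export
predict_points <- function(chain, lat, lon,
                           n_samples = chain$config$n_predict_samples,
                           seed = chain$config$seed + 1L) {
  stopifnot(inherits(chain, "mbg_chain"), length(lat) == length(lon))
  set.seed(seed)
  cfg <- chain$config
  m <- length(lat)
  n <- length(chain$data$pos)
  obs <- cbind(chain$data$latitude, chain$data$longitude)
  tgt <- cbind(lat, lon)
  D_oo <- chain$D
  D_to <- gc_distance_matrix(tgt, obs)
  D_tt <- gc_distance_matrix(tgt)
  idx <- draw_indices(nrow(chain$draws), n_samples)
  out <- matrix(NA_real_, n_samples, m)
  for (s in seq_along(idx)) {
    i <- idx[s]
    mu <- chain$draws$mean[i]
    sill <- chain$draws$sill[i]
    rng <- chain$draws$range_km[i]
    nug <- chain$draws$nugget[i]
    f <- chain$latent[i, ] - mu
    if (sill <= 0) {
      ## no spatial correlation: target field is independent noise
      z <- mu + stats::rnorm(m, sd = sqrt(nug))
      out[s, ] <- stats::plogis(z)
      next
    }
    S_oo <- cov_matrix(D_oo, sill, rng, cfg$smoothness, nug, cfg$jitter)
    ## cross- and target covariance carry no nugget off their diagonal
    C_to <- sill * matern_corr(D_to, rng, cfg$smoothness)
    S_tt <- cov_matrix(D_tt, sill, rng, cfg$smoothness, nug, cfg$jitter)
    U_oo <- tryCatch(chol(S_oo), error = function(e)
      stop("conditional covariance not positive definite", call. = FALSE))
    ## V = L^{-1} C_ot ; conditional covariance = S_tt - V'V
    V <- backsolve(U_oo, t(C_to), transpose = TRUE)
    w <- backsolve(U_oo, f, transpose = TRUE)
    cmean <- mu + drop(crossprod(V, w))
    ccov <- S_tt - crossprod(V)
    diag(ccov) <- diag(ccov) + cfg$jitter * sill + 1e-12
    U_c <- tryCatch(chol(ccov), error = function(e)
      stop("conditional covariance not positive definite after jitter",
           call. = FALSE))
    out[s, ] <- stats::plogis(cmean + drop(crossprod(U_c, stats::rnorm(m))))
  }
  structure(list(samples = out,
                 coords = tibble::tibble(lat = lat, lon = lon),
                 grid = NULL,
                 provenance = object_md5(unclass(cfg))),
            class = "posterior_field_samples")
}

#' Posterior-predictive frequency samples on a grid
#'
#' [predict_points()] evaluated at every pixel centre of `grid`.
#'
#' @param chain An `mbg_chain`.
#' @param grid A [grid_spec()].
#' @param n_samples,seed See [predict_points()].
#' @return A `posterior_field_samples` whose `grid` field is set, so each
#'   sample row can be reshaped with the grid.
#' @export
predict_grid <- function(chain, grid,
                         n_samples = chain$config$n_predict_samples,
                         seed = chain$config$seed + 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  ctr <- pixel_centers(grid)
  out <- predict_points(chain, ctr$lat, ctr$lon, n_samples = n_samples,
                        seed = seed)
  out$grid <- grid
  out
}

#' Pixelwise summary maps of a posterior field
#'
#' Mean, median and quartiles per pixel; percentiles use linear
#' interpolation between order statistics (R quantile type 7), which the
#' IQR maps depend on.
#'
#' @param field A `posterior_field_samples` with >= 2 samples.
#' @return A `summary_maps` object: matrices (or vectors when the field
#'   has no grid) `mean`, `median`, `q25`, `q75`, `iqr_width`.
#' @export
summarize_field <- function(field) {
  stopifnot(inherits(field, "posterior_field_samples"))
  if (nrow(field$samples) < 2L)
    stop("need at least 2 posterior samples", call. = FALSE)
  qs <- apply(field$samples, 2L, stats::quantile,
              probs = c(0.25, 0.5, 0.75), type = q_type, names = FALSE)
  shape <- function(v) if (is.null(field$grid)) v
                       else grid_matrix(v, field$grid)
  structure(list(mean = shape(colMeans(field$samples)),
                 median = shape(qs[2, ]),
                 q25 = shape(qs[1, ]),
                 q75 = shape(qs[3, ]),
                 iqr_width = shape(qs[3, ] - qs[1, ]),
                 grid = field$grid),
            class = "summary_maps")
}
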