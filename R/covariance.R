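#' Radius of the spherical Earth used throughout (km)
#'
#' IUGG mean radius, 6371.0088 km.
#' @return A scalar, km.
#' @export
earth_radius_km <- function() 6371.0088

#' Great-circle distance between points (km)
#'
#' Haversine distance on a sphere of radius [earth_radius_km()], via
#' \pkg{geosphere}.  Accepts single points `c(lat, lon)` or two-column
#' matrices `(lat, lon)` recycled row-wise.
#'
#' @param a,b Points as `c(lat, lon)` or matrices with columns lat, lon.
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_km(c(0, 0), c(0, 90))  # quarter great circle
#' @export
great_circle_km <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  stopifnot(ncol(a) == 2L, ncol(b) == 2L,
            all(abs(a[, 1]) <= 90), all(abs(b[, 1]) <= 90),
            all(abs(a[, 2]) <= 180), all(abs(b[, 2]) <= 180))
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = earth_radius_km())
}

#' Pairwise great-circle distance matrix (km)
#'
#' @param x Matrix with columns lat, lon.
#' @param y Optional second matrix; defaults to `x`.
#' @return `nrow(x) x nrow(y)` matrix of distances in km.
#' @export
gc_distance_matrix <- function(x, y = x) {
  x <- rbind(x); y <- rbind(y)
  stopifnot(ncol(x) == 2L, ncol(y) == 2L)
  geosphere::distm(x[, 2:1, drop = FALSE], y[, 2:1, drop = FALSE],
                   fun = function(p, q)
                     geosphere::distHaversine(p, q, r = earth_radius_km()))
}

matern_corr <- function(d, range_km, smoothness) {
  stopifnot(range_km > 0, smoothness > 0)
  if (any(d < 0)) stop("negative distance", call. = FALSE)
  if (smoothness == 0.5) {
    exp(-d / range_km)
  } else if (smoothness == 1.5) {
    s <- sqrt(3) * d / range_km
    (1 + s) * exp(-s)
  } else if (smoothness == 2.5) {
    s <- sqrt(5) * d / range_km
    (1 + s + s^2 / 3) * exp(-s)
  } else {
    s <- sqrt(2 * smoothness) * d / range_km
    out <- 2^(1 - smoothness) / gamma(smoothness) *
      s^smoothness * besselK(s, smoothness)
    out[s == 0] <- 1
    out
  }
}

#' Matern covariance function over great-circle distance
#'
#' `sill * rho(d) + nugget * 1(d = 0)` where `rho` is the Matern
#' correlation with the sqrt(2*nu) length-scale convention, so that
#' smoothness 1/2 gives `sill * exp(-d/range_km)`.
#'
#' @param d Distance(s), km, non-negative.
#' @param sill Partial sill (process variance), >= 0.
#' @param range_km Range parameter (km), > 0.
#' @param smoothness Matern order nu (> 0); 0.5, 1.5, 2.5 use closed forms.
#' @param nugget Micro-scale variance added at zero lag, >= 0.
#' @return Covariance value(s).
#' @examples
#' matern_cov(0, sill = 1, range_km = 500, nugget = 0.1)   # 1.1
#' matern_cov(500, sill = 2, range_km = 500, smoothness = 0.5)  # 2/e
#' @export
matern_cov <- function(d, sill, range_km, smoothness = 1.5, nugget = 0) {
  stopifnot(sill >= 0, nugget >= 0)
  if (any(d < 0)) stop("negative distance", call. = FALSE)
  sill * matern_corr(d, range_km, smoothness) + nugget * (d == 0)
}

## covariance matrix over a precomputed distance matrix, with diagonal
## stabiliser jitter * sill (plus a tiny absolute floor when sill = 0)
cov_matrix <- function(D, sill, range_km, smoothness, nugget, jitter = 1e-8) {
  n <- nrow(D)
  S <- if (sill > 0) sill * matern_corr(D, range_km, smoothness)
       else matrix(0, n, n)
  diag(S) <- diag(S) + nugget + jitter * sill + 1e-12
  S
}
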