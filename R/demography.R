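## Hardy-Weinberg genotype frequencies and population/birth-rate-weighted
## areal integrals of the posterior frequency field.

#' Hardy-Weinberg genotype frequencies from an allele frequency
#'
#' Under random mating at C-allele frequency `q`, genotype proportions are
#' `(1-q)^2`, `2q(1-q)` and `q^2` for AA, AC and CC.
#'
#' @param q Allele frequency (vectorised), in [0, 1].
#' @return A tibble with columns `f_AA`, `f_AC`, `f_CC` summing to 1.
#' @examples
#' hwe_genotype_freqs(0.13)  # f_AC = 0.2262, f_CC = 0.0169
#' @export
hwe_genotype_freqs <- function(q) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("allele frequency must lie in [0, 1]", call. = FALSE)
  tibble::tibble(f_AA = (1 - q)^2, f_AC = 2 * q * (1 - q), f_CC = q^2)
}

#' Per-pixel annual births from population and crude birth rates
#'
#' `births(pixel) = pop(pixel) * cbr(unit containing the pixel)`.  A
#' population raster at an integer multiple finer resolution than the
#' mask's grid is first sum-aggregated with [aggregate_sum()].
#'
#' @param pop A `population_surface`.
#' @param mask A `country_mask` on the same grid (or on a grid the
#'   population aggregates onto exactly).
#' @param demographics Tibble with `unit_id` and `cbr` covering every unit
#'   in the mask.
#' @return Matrix of births per pixel per year on the mask's grid.
#' @export
births_surface <- function(pop, mask, demographics) {
  stopifnot(inherits(pop, "population_surface"),
            inherits(mask, "country_mask"))
  popm <- pop$pop
  if (!grids_identical(pop$grid, mask$grid)) {
    fac <- nrow(popm) / mask$grid$n_rows
    if (fac != as.integer(fac) || ncol(popm) / mask$grid$n_cols != fac)
      stop("population grid is not an integer refinement of the mask grid",
           call. = FALSE)
    popm <- aggregate_sum(popm, as.integer(fac))
  }
  units <- as.vector(mask$units)
  present <- unique(units[!is.na(units)])
  missing <- setdiff(present, demographics$unit_id)
  if (length(missing))
    stop("no crude birth rate for unit(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cbr <- demographics$cbr[match(units, demographics$unit_id)]
  cbr[is.na(units)] <- 0
  grid_matrix(as.vector(popm) * cbr, mask$grid)
}

#' Areal posterior-predictive distribution of affected newborns
#'
#' For each posterior field draw `s`, the expected annual AC and CC
#' newborns in a unit are the birth-weighted Hardy-Weinberg integrals
#' `AC_s = sum 2 q_s (1-q_s) births` and `CC_s = sum q_s^2 births` over
#' the unit's pixels.  The full per-draw vectors are returned so that
#' uncertainty propagates into any downstream summary.
#'
#' @param field A `posterior_field_samples` on a grid.
#' @param births Births-per-pixel matrix from [births_surface()].
#' @param mask A `country_mask` on the same grid.
#' @param unit Unit label to integrate over.
#' @return Tibble with one row per posterior draw: `draw`, `ac`, `cc`.
#' @export
areal_newborn_ppd <- function(field, births, mask, unit) {
  stopifnot(inherits(field, "posterior_field_samples"),
            inherits(mask, "country_mask"), !is.null(field$grid))
  idx <- which(as.vector(mask$units) == unit)
  if (!length(idx)) stop("unit has no pixels: ", unit, call. = FALSE)
  q <- field$samples[, idx, drop = FALSE]
  b <- as.vector(births)[idx]
  tibble::tibble(draw = seq_len(nrow(q)),
                 ac = drop((2 * q * (1 - q)) %*% b),
                 cc = drop((q * q) %*% b))
}

summarize_ppd_draws <- function(x) {
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = q_type, names = FALSE)
  c(q25 = qs[1], median = qs[2], q75 = qs[3])
}

#' Areal estimate table of affected newborns
#'
#' Per-unit medians and interquartile ranges of annual AC and CC newborns
#' and of the birth-weighted mean allele frequency, plus a regional row
#' computed from the per-draw sum across units on the same field draws
#' (so per-draw national totals add exactly to the regional total).
#'
#' @param field A `posterior_field_samples` on a grid.
#' @param births Births matrix from [births_surface()].
#' @param mask A `country_mask`.
#' @param demographics Tibble with `unit_id`, `cbr` (and optionally
#'   `total_pop`, echoed into the table).
#' @param region_label Label of the all-units row (default `"REGION"`);
#'   `NULL` suppresses it.
#' @return An `areal_estimate_table` tibble: `unit_id`, `total_pop`,
#'   `cbr`, `af_median`, `af_q25`, `af_q75`, and `median`/`q25`/`q75` for
#'   `ac` and `cc` newborns per year.
#' @export
newborn_estimates <- function(field, births, mask, demographics,
                              region_label = "REGION") {
  units <- demographics$unit_id[demographics$unit_id %in%
                                  as.vector(mask$units)]
  ppds <- lapply(units, function(u)
    areal_newborn_ppd(field, births, mask, u))
  names(ppds) <- units
  b <- as.vector(births)
  row_for <- function(u, ppd) {
    idx <- which(as.vector(mask$units) == u)
    bw <- b[idx]
    af <- if (sum(bw) > 0) drop(field$samples[, idx, drop = FALSE] %*%
                                  (bw / sum(bw)))
          else rowMeans(field$samples[, idx, drop = FALSE])
    a <- summarize_ppd_draws(ppd$ac)
    cc <- summarize_ppd_draws(ppd$cc)
    f <- summarize_ppd_draws(af)
    tibble::tibble(unit_id = u,
                   total_pop = demographics$total_pop[
                     match(u, demographics$unit_id)],
                   cbr = demographics$cbr[match(u, demographics$unit_id)],
                   af_median = f[["median"]], af_q25 = f[["q25"]],
                   af_q75 = f[["q75"]],
                   ac_median = a[["median"]], ac_q25 = a[["q25"]],
                   ac_q75 = a[["q75"]],
                   cc_median = cc[["median"]], cc_q25 = cc[["q25"]],
                   cc_q75 = cc[["q75"]])
  }
  out <- do.call(rbind, lapply(units, function(u) row_for(u, ppds[[u]])))
  if (!is.null(region_label)) {
    reg_ac <- Reduce(`+`, lapply(ppds, `[[`, "ac"))
    reg_cc <- Reduce(`+`, lapply(ppds, `[[`, "cc"))
    inside <- !is.na(as.vector(mask$units))
    bw <- b[inside]
    af <- drop(field$samples[, inside, drop = FALSE] %*% (bw / sum(bw)))
    a <- summarize_ppd_draws(reg_ac)
    cc <- summarize_ppd_draws(reg_cc)
    f <- summarize_ppd_draws(af)
    out <- rbind(out, tibble::tibble(
      unit_id = region_label,
      total_pop = sum(demographics$total_pop[match(units,
                                                   demographics$unit_id)]),
      cbr = NA_real_,
      af_median = f[["median"]], af_q25 = f[["q25"]], af_q75 = f[["q75"]],
      ac_median = a[["median"]], ac_q25 = a[["q25"]], ac_q75 = a[["q75"]],
      cc_median = cc[["median"]], cc_q25 = cc[["q25"]],
      cc_q75 = cc[["q75"]]))
  }
  structure(out, class = c("areal_estimate_table", class(out)),
            ppds = ppds)
}

#' Summarise per-unit posterior draw vectors
#'
#' Medians and quartiles (type-7 percentiles, as everywhere in the
#' package) of per-draw areal newborn counts.
#'
#' @param ppds Named list of per-unit draw tibbles from
#'   [areal_newborn_ppd()] (>= 2 draws each).
#' @return Tibble with `unit_id` and `median`/`q25`/`q75` per genotype.
#' @export
summarize_estimates <- function(ppds) {
  stopifnot(is.list(ppds), length(ppds) > 0)
  rows <- lapply(names(ppds), function(u) {
    ppd <- ppds[[u]]
    if (nrow(ppd) < 2L) stop("need >= 2 draws per unit", call. = FALSE)
    a <- summarize_ppd_draws(ppd$ac)
    cc <- summarize_ppd_draws(ppd$cc)
    tibble::tibble(unit_id = u,
                   ac_median = a[["median"]], ac_q25 = a[["q25"]],
                   ac_q75 = a[["q75"]],
                   cc_median = cc[["median"]], cc_q25 = cc[["q25"]],
                   cc_q75 = cc[["q75"]])
  })
  do.call(rbind, rows)
}

#' Monte Carlo standard error of repeated areal summaries
#'
#' Repeats a stochastic areal computation (e.g. re-sampling which
#' posterior draws enter the areal integral) and reports the sample
#' standard deviation (n - 1 denominator) of the repeated summaries.
#'
#' @param estimate_fn Function of a single integer seed returning a named
#'   numeric vector of summaries (e.g. per-unit medians).
#' @param n_repeats Number of repeats (>= 2; default 10).
#' @param seeds Optional integer vector of seeds, length `n_repeats`.
#' @return Named numeric vector of standard errors, one per summary.
#' @examples
#' monte_carlo_se(function(s) c(x = c(10, 12, 14)[s]), n_repeats = 3)  # x = 2
#' @export
monte_carlo_se <- function(estimate_fn, n_repeats = 10, seeds = NULL) {
  if (n_repeats < 2) stop("need at least 2 repeats", call. = FALSE)
  seeds <- seeds %||% seq_len(n_repeats)
  stopifnot(length(seeds) == n_repeats)
  reps <- do.call(rbind, lapply(seeds, function(s) estimate_fn(s)))
  apply(reps, 2L, stats::sd)
}

#' Resample the posterior field draws entering an areal table
#'
#' The stochastic kernel repeated by [monte_carlo_se()]: draws a bootstrap
#' subset of field samples and recomputes per-unit medians.
#'
#' @param field,births,mask,demographics As in [newborn_estimates()].
#' @param seed Integer seed for the resampling.
#' @return Named numeric vector of per-unit AC and CC medians.
#' @export
resampled_medians <- function(field, births, mask, demographics, seed) {
  set.seed(seed)
  idx <- sample.int(nrow(field$samples), replace = TRUE)
  f2 <- field
  f2$samples <- field$samples[idx, , drop = FALSE]
  tab <- newborn_estimates(f2, births, mask, demographics,
                           region_label = "REGION")
  stats::setNames(c(tab$ac_median, tab$cc_median),
                  c(paste0("ac_", tab$unit_id), paste0("cc_", tab$unit_id)))
}
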