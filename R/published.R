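## Helpers over the published national estimate table that ships with the
## package: simple share and ratio arithmetic used for cross-checking an
## areal estimate table against previously published figures.

#' Published AFRO national estimates of HbC newborns (2010)
#'
#' The published per-country table of HbC allele-frequency medians and
#' IQRs, AC and CC newborn estimates, national populations and crude
#' birth rates for the WHO African region, including the regional row and
#' an earlier conservative CC reference estimate (`reference_cc`, from
#' the 2008 service-indicator literature).  Shipped as plain CSV in
#' `inst/extdata/afro_estimates_2010.csv`.
#'
#' @return A tibble, one row per country plus the `"AFRO region"` row.
#' @export
load_afro_table <- function() {
  path <- system.file("extdata", "afro_estimates_2010.csv",
                      package = "hbcmap")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Share of regional newborns contributed by selected units
#'
#' `sum(unit medians) / regional median`, for an areal estimate table
#' with `ac_median`/`cc_median` columns (the published table or one
#' produced by [newborn_estimates()]).
#'
#' @param table Estimate table.
#' @param units Character vector of `unit_id` values.
#' @param genotype `"ac"` or `"cc"`.
#' @param region Label of the regional row (default `"AFRO region"`).
#' @return Proportion in [0, 1] (can exceed 1 if medians are not
#'   additive, as medians of sums need not equal sums of medians).
#' @export
newborn_share <- function(table, units, genotype = c("ac", "cc"),
                          region = "AFRO region") {
  genotype <- match.arg(genotype)
  col <- paste0(genotype, "_median")
  stopifnot(col %in% names(table), all(units %in% table$unit_id),
            region %in% table$unit_id)
  sum(table[[col]][table$unit_id %in% units]) /
    table[[col]][table$unit_id == region]
}

#' Ratio of a regional quartile to a reference estimate
#'
#' E.g. the ratio of the regional 25%- or 75%-quartile CC newborn count to
#' an earlier published point estimate.
#'
#' @param table Estimate table.
#' @param quartile `"q25"`, `"median"` or `"q75"`.
#' @param genotype `"ac"` or `"cc"`.
#' @param reference Reference value (denominator).
#' @param region Label of the regional row.
#' @return The ratio.
#' @export
quartile_ratio <- function(table, quartile = c("q25", "median", "q75"),
                           genotype = c("ac", "cc"), reference,
                           region = "AFRO region") {
  quartile <- match.arg(quartile)
  genotype <- match.arg(genotype)
  stopifnot(is.numeric(reference), reference > 0)
  col <- paste0(genotype, "_", quartile)
  table[[col]][table$unit_id == region] / reference
}
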