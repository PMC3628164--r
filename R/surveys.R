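## Survey database: data model, I/O, inclusion filtering, per-location
## deduplication and summary statistics for HbC allele-frequency surveys.

survey_fields <- c("source_id", "latitude", "longitude", "year",
                   "n_individuals", "n_AA", "n_AC", "n_CC",
                   "diagnostic_method", "representative")

## diagnostic method ranking used for deduplication: earlier groups are
## preferred; matching is case-insensitive substring
default_method_ranking <- function() {
  list(molecular      = c("molecular", "dna", "pcr", "sequenc"),
       hplc_ief       = c("hplc", "ief", "isoelectric"),
       electrophoresis = c("electrophoresis", "cellulose"))
}

method_rank <- function(method, ranking = default_method_ranking()) {
  m <- tolower(trimws(as.character(method)))
  r <- rep.int(length(ranking) + 1L, length(m))
  for (i in rev(seq_along(ranking))) {
    hit <- Reduce(`|`, lapply(ranking[[i]], function(p) grepl(p, m, fixed = TRUE)))
    r[hit] <- i
  }
  r[is.na(m) | m == ""] <- length(ranking) + 1L
  r
}

#' Convert genotype counts to allele counts
#'
#' Each CC individual carries two C (`pos`) alleles and each AC individual
#' one; likewise for A (`neg`) alleles.  Surveys reporting the absence of
#' any haemoglobin variant are encoded as all-AA, giving `pos = 0`.
#'
#' @param n_AA,n_AC,n_CC Non-negative genotype counts (vectorised).
#' @return A tibble with columns `pos` and `neg`;
#'   `pos + neg = 2 * (n_AA + n_AC + n_CC)`.
#' @examples
#' allele_counts(90, 9, 1)    # pos = 11, neg = 189
#' allele_counts(100, 0, 0)   # zero-variant survey: pos = 0
#' @export
allele_counts <- function(n_AA, n_AC, n_CC) {
  if (any(c(n_AA, n_AC, n_CC) < 0, na.rm = TRUE))
    stop("genotype counts must be non-negative", call. = FALSE)
  tibble::tibble(pos = 2 * n_CC + n_AC, neg = 2 * n_AA + n_AC)
}

#' Observed allele frequency of surveys
#'
#' @param collection A `survey_collection` (or any data frame with `pos`
#'   and `neg` columns).
#' @return Numeric vector `pos / (pos + neg)`.
#' @export
observed_frequency <- function(collection) {
  with(collection, pos / (pos + neg))
}

validate_survey_rows <- function(df) {
  reasons <- rep.int(NA_character_, nrow(df))
  note <- function(bad, msg) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- msg
  }
  note(!is.finite(df$latitude) | abs(df$latitude) > 90,
       "latitude outside [-90, 90]")
  note(!is.finite(df$longitude) | abs(df$longitude) > 180,
       "longitude outside [-180, 180]")
  note(!is.finite(df$n_individuals) | df$n_individuals < 1,
       "n_individuals < 1")
  has_geno <- !is.na(df$n_AA) & !is.na(df$n_AC) & !is.na(df$n_CC)
  note(has_geno & (df$n_AA < 0 | df$n_AC < 0 | df$n_CC < 0),
       "negative genotype count")
  note(has_geno & (df$n_AA + df$n_AC + df$n_CC != df$n_individuals),
       "genotype counts do not sum to n_individuals")
  note(!has_geno & is.na(df$allele_frequency),
       "neither genotype counts nor allele_frequency given")
  note(!is.na(df$allele_frequency) &
         (df$allele_frequency < 0 | df$allele_frequency > 1),
       "allele_frequency outside [0, 1]")
  reasons
}

#' Assemble a survey collection from a data frame
#'
#' Enforces the survey invariants row by row; offending rows are dropped
#' and reported (row index plus violated rule) in the `rejected` attribute
#' and as a warning.  Rows carrying only an allele frequency are accepted
#' by back-computing `pos = round(2 * n * frequency)`; these are flagged
#' in the collection's provenance.
#'
#' @param df Data frame with the survey columns (`source_id`, `latitude`,
#'   `longitude`, `year`, `n_individuals`, `n_AA`, `n_AC`, `n_CC`,
#'   `diagnostic_method`, `representative`; optionally
#'   `allele_frequency`).
#' @param provenance Free-text metadata attached to the collection.
#' @return A `survey_collection`: a tibble with the survey columns plus
#'   derived `pos`/`neg`, in input order.
#' @export
as_survey_collection <- function(df, provenance = "") {
  df <- tibble::as_tibble(df)
  for (f in survey_fields)
    if (!f %in% names(df)) df[[f]] <- NA
  if (!"allele_frequency" %in% names(df)) df$allele_frequency <- NA_real_
  for (f in c("latitude", "longitude", "year", "n_individuals",
              "n_AA", "n_AC", "n_CC", "allele_frequency"))
    df[[f]] <- as.numeric(df[[f]])
  df$representative <- ifelse(is.na(df$representative), TRUE,
                              as.logical(df$representative))
  reasons <- if (nrow(df)) validate_survey_rows(df) else character(0)
  rejected <- tibble::tibble(row = which(!is.na(reasons)),
                             reason = reasons[!is.na(reasons)])
  if (nrow(rejected)) {
    warning(sprintf("%d survey row(s) rejected: %s", nrow(rejected),
                    paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
                          collapse = "; ")), call. = FALSE)
    df <- df[is.na(reasons), , drop = FALSE]
  }
  backcomputed <- with(df, is.na(n_AA) & !is.na(allele_frequency))
  if (any(backcomputed)) {
    n <- df$n_individuals[backcomputed]
    pos <- round(2 * n * df$allele_frequency[backcomputed])
    ## reconstruct a consistent genotype split: homozygotes first
    df$n_CC[backcomputed] <- pos %/% 2
    df$n_AC[backcomputed] <- pos %% 2
    df$n_AA[backcomputed] <- n - df$n_CC[backcomputed] - df$n_AC[backcomputed]
    provenance <- paste0(provenance,
                         sprintf(" [%d survey(s) back-computed from allele frequency]",
                                 sum(backcomputed)))
  }
  ac <- allele_counts(df$n_AA, df$n_AC, df$n_CC)
  df$pos <- ac$pos
  df$neg <- ac$neg
  df$allele_frequency <- NULL
  structure(df, class = c("survey_collection", class(df)),
            provenance = trimws(provenance), rejected = rejected)
}

#' Read a survey table from delimited text
#'
#' @param path Path to a delimited text file (UTF-8) whose header names the
#'   survey columns; coordinates in decimal degrees WGS84.
#' @param delim Field delimiter (default comma).
#' @return A `survey_collection`; rejected rows are reported via the
#'   `rejected` attribute and a warning.  An empty (header-only) file
#'   yields an empty collection with a warning.
#' @export
load_surveys <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  mandatory <- c("source_id", "latitude", "longitude", "n_individuals")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    warning("survey file contains a header but no rows", call. = FALSE)
  as_survey_collection(df, provenance = paste0("loaded from ", path))
}

#' Write a survey collection as delimited text
#'
#' @param collection A `survey_collection`.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_surveys <- function(collection, path, delim = ",") {
  readr::write_delim(collection[, c(survey_fields, "pos", "neg")], path,
                     delim = delim)
  invisible(path)
}

#' Keep one survey per location
#'
#' When several surveys share a location (coordinates equal after rounding
#' to 4 decimal places, about 11 m) only the most representative one is
#' kept, ranked lexicographically by (1) larger sample size, (2) more
#' recent year, (3) diagnostic method (molecular, then HPLC/IEF, then
#' electrophoresis, then unknown), (4) first occurrence.  Deterministic;
#' dropped surveys are recorded in the `dropped` attribute.
#'
#' @param collection A `survey_collection`.
#' @param method_ranking Ordered list of character vectors of method
#'   patterns, most preferred first.
#' @return The deduplicated `survey_collection`, in original file order.
#' @export
deduplicate_by_location <- function(collection,
                                    method_ranking = default_method_ranking()) {
  if (nrow(collection) == 0L) return(collection)
  key <- paste(round(collection$latitude, 4), round(collection$longitude, 4))
  rank_m <- method_rank(collection$diagnostic_method, method_ranking)
  ord <- order(key,
               -collection$n_individuals,
               -ifelse(is.na(collection$year), -Inf, collection$year),
               rank_m,
               seq_len(nrow(collection)))
  keep_idx <- ord[!duplicated(key[ord])]
  dropped <- sort(setdiff(seq_len(nrow(collection)), keep_idx))
  out <- collection[sort(keep_idx), , drop = FALSE]
  attr(out, "provenance") <- attr(collection, "provenance")
  attr(out, "rejected") <- attr(collection, "rejected")
  attr(out, "dropped") <- collection[dropped, , drop = FALSE]
  if (length(dropped))
    message(sprintf("deduplicate_by_location: dropped %d of %d surveys",
                    length(dropped), nrow(collection)))
  out
}

#' Summary statistics of a survey collection
#'
#' @param collection A non-empty `survey_collection`.
#' @return A one-row tibble: `n_sources`, `n_locations`,
#'   `total_individuals`, `mean_sample_size` (= total / locations),
#'   `min_sample_size`, `max_sample_size`, `fraction_under_1000`,
#'   `fraction_zero_variant` (share of surveys with `pos = 0`).
#' @export
summarize_database <- function(collection) {
  if (nrow(collection) == 0L)
    stop("cannot summarise an empty survey collection", call. = FALSE)
  key <- paste(round(collection$latitude, 4), round(collection$longitude, 4))
  total <- sum(collection$n_individuals)
  n_loc <- length(unique(key))
  tibble::tibble(
    n_sources = length(unique(collection$source_id)),
    n_locations = n_loc,
    total_individuals = total,
    mean_sample_size = total / n_loc,
    min_sample_size = min(collection$n_individuals),
    max_sample_size = max(collection$n_individuals),
    fraction_under_1000 = mean(collection$n_individuals < 1000),
    fraction_zero_variant = mean(collection$pos == 0))
}
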