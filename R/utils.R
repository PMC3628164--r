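#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage-specific seed from a root seed
#'
#' Named substreams let pipeline stages be rerun independently while all
#' randomness remains traceable to one root seed.  The derived seed is a
#' deterministic 31-bit integer.
#'
#' @param seed Root integer seed.
#' @param stage Character stage label (e.g. `"simulate"`, `"fit"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

## md5 of an arbitrary R object via its canonical YAML/serialised text form
object_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}

## quantile convention used throughout (linear interpolation between order
## statistics, R's type 7); IQR maps and areal tables depend on it
q_type <- 7L

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
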