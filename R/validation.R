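## Hold-out validation: split, predict at held-out sites, error metrics.

#' Random train/test split of a survey collection
#'
#' Uniform sampling without replacement; the test-set size is
#' `fraction * n` rounded half up.
#'
#' @param collection A non-empty `survey_collection`.
#' @param fraction Held-out proportion in [0, 1); default 0.10.
#' @param seed Integer seed.
#' @return A `holdout_split`: list with `train`, `test` (disjoint
#'   collections covering the input), `fraction`, `seed`.
#' @export
holdout_split <- function(collection, fraction = 0.10, seed = 1L) {
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)", call. = FALSE)
  n <- nrow(collection)
  if (n == 0L) stop("empty survey collection", call. = FALSE)
  n_test <- floor(fraction * n + 0.5)  # round half up
  if (n_test == 0L)
    warning("hold-out fraction yields an empty test set", call. = FALSE)
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  structure(list(train = collection[setdiff(seq_len(n), test_idx), ,
                                    drop = FALSE],
                 test = collection[test_idx, , drop = FALSE],
                 fraction = fraction, seed = as.integer(seed)),
            class = "holdout_split")
}

#' Prediction residuals at held-out sites
#'
#' Sign convention: `predicted - observed`, in allele-frequency units.
#'
#' @param predicted Posterior mean frequency per test site.
#' @param observed Observed frequency per test site (`pos / (pos + neg)`).
#' @return Numeric residual vector.
#' @export
prediction_errors <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ", call. = FALSE)
  predicted - observed
}

#' Hold-out error metrics
#'
#' Mean error (bias), mean absolute error (accuracy) and root mean square
#' error (precision) of prediction residuals, each with a cross-site
#' dispersion companion: the sample standard deviations of `r`, `|r|` and
#' `r^2` respectively.  (The dispersion convention is this package's
#' interpretation of the "+/-" values that typically accompany such
#' metrics; sources rarely define them.)
#'
#' @param residuals Non-empty numeric vector (predicted - observed).
#' @return One-row tibble: `mean_error`, `mean_absolute_error`,
#'   `rms_error` and `me_dispersion`, `mae_dispersion`,
#'   `rmse_dispersion`.
#' @examples
#' error_metrics(c(0.01, -0.02, 0.03))
#' @export
error_metrics <- function(residuals) {
  if (!length(residuals)) stop("empty residual vector", call. = FALSE)
  r <- residuals
  tibble::tibble(
    mean_error = mean(r),
    mean_absolute_error = mean(abs(r)),
    rms_error = sqrt(mean(r^2)),
    me_dispersion = stats::sd(r),
    mae_dispersion = stats::sd(abs(r)),
    rmse_dispersion = stats::sd(r^2))
}

#' Full hold-out validation loop
#'
#' Splits the collection, refits the model on the training surveys,
#' predicts the posterior mean frequency at the test sites' exact
#' coordinates (not the nearest pixel centre, removing grid-discretisation
#' error from the metrics) and computes the error metrics.
#'
#' @param collection A `survey_collection` with >= 10 surveys.
#' @param config An [mbg_config()].
#' @param fraction Held-out proportion (default 0.10).
#' @param seed Seed for the split (the fit uses `config$seed`).
#' @return List: `metrics` (tibble from [error_metrics()]), `split`,
#'   `residuals`, `predicted`, `observed`, `chain`.
#' @export
validate_model <- function(collection, config = mbg_config(),
                           fraction = 0.10, seed = 1L) {
  if (nrow(collection) < 10L)
    stop("need at least 10 surveys for hold-out validation", call. = FALSE)
  split <- holdout_split(collection, fraction, seed)
  chain <- mbg_fit(split$train, config)
  pred <- predict_points(chain, split$test$latitude, split$test$longitude)
  predicted <- colMeans(pred$samples)
  observed <- observed_frequency(split$test)
  residuals <- prediction_errors(predicted, observed)
  list(metrics = error_metrics(residuals), split = split,
       residuals = residuals, predicted = predicted, observed = observed,
       chain = chain)
}
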