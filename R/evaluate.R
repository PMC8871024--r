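# Evaluation metrics: RMSE, regression coefficient R (Pearson correlation of
# predicted vs actual), fractions of records with |error| <= threshold, and a
# signed-error histogram on unit-width integer bins.

#' Evaluate a trained model on a cohort
#'
#' Computes `rmse = sqrt(mean((yhat - y)^2))`, the regression coefficient R
#' (Pearson correlation between predictions and observations), the fraction
#' of records whose absolute prediction error is at or below each threshold,
#' and a signed-error histogram. Predictions are used unrounded by default;
#' set `round_predictions = TRUE` to round them to integer counts first.
#'
#' @param model an `ovr_model`.
#' @param cohort a cohort data frame carrying the outcome column.
#' @param thresholds absolute-error thresholds (oocytes), default `c(3, 5)`.
#' @param scope `"full_cohort"` to evaluate every record, or `"test_only"` to
#'   restrict to the model's held-out test rows (requires the split stored in
#'   the model diagnostics).
#' @param round_predictions round predictions to integers before scoring.
#' @param schema a [cohort_schema()].
#' @return A list of class `ovr_eval`: `rmse`, `r_coef` (NA with a
#'   `degenerate` flag when predictions or observations have zero variance),
#'   `frac_le` (named numeric), `error_histogram` (data frame of bin centers
#'   and counts), `n`, `scope`.
#' @export
evaluate_model <- function(model, cohort, thresholds = c(3, 5),
                           scope = c("full_cohort", "test_only"),
                           round_predictions = FALSE,
                           schema = cohort_schema()) {
  scope <- match.arg(scope)
  if (nrow(cohort) == 0) stop("cannot evaluate on an empty cohort")
  if (scope == "test_only") {
    idx <- model$diagnostics$split$test
    if (is.null(idx))
      stop("model carries no train/test split; use scope = 'full_cohort'")
    cohort <- cohort[idx, , drop = FALSE]
  }
  y <- cohort[[schema$outcome]]
  yhat <- suppressWarnings(stats::predict(model, cohort))
  if (round_predictions) yhat <- round(yhat)
  err <- yhat - y
  rmse <- sqrt(mean(err^2))
  degenerate <- stats::sd(yhat) == 0 || stats::sd(y) == 0
  r_coef <- if (degenerate) NA_real_ else stats::cor(yhat, y)
  thresholds <- sort(thresholds)
  frac_le <- vapply(thresholds, function(t) mean(abs(err) <= t), numeric(1))
  names(frac_le) <- paste0("le_", thresholds)
  bins <- seq(floor(min(err)), ceiling(max(err)))
  counts <- tabulate(findInterval(err, bins - 0.5), nbins = length(bins))
  structure(
    list(rmse = rmse, r_coef = r_coef, degenerate = degenerate,
         frac_le = frac_le,
         error_histogram = data.frame(error = bins, count = counts),
         n = length(y), scope = scope),
    class = "ovr_eval"
  )
}

#' @export
print.ovr_eval <- function(x, ...) {
  cat("Model evaluation (", x$scope, ", n = ", x$n, ")\n", sep = "")
  cat("  RMSE:", round(x$rmse, 3), "oocytes\n")
  cat("  regression coefficient R:",
      if (is.na(x$r_coef)) "undefined (zero variance)" else round(x$r_coef, 3),
      "\n")
  for (nm in names(x$frac_le)) {
    t <- sub("le_", "", nm)
    cat(sprintf("  |error| <= %s: %.2f%%\n", t, 100 * x$frac_le[[nm]]))
  }
  invisible(x)
}
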