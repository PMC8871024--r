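# Perturbation-based feature importance: the mean impact value (MIV) of a
# feature is the cohort-average change in the model prediction when that
# feature is multiplied by 1.1 versus 0.9 (all other features held at their
# observed values); the normalized MIV (NMIV) divides the MIV vector by its
# maximum absolute entry, so the top-ranked feature always has |NMIV| = 1.
# The perturbation is applied to the RAW feature value (integer code for
# categoricals) before the model's internal scaling, and perturbed values are
# deliberately not clipped back into the training range.

#' Mean impact value of one feature
#'
#' `miv_i = mean over records of [F(..., 1.1 * h_i, ...) - F(..., 0.9 * h_i, ...)]`
#' where F is the trained predictor and the mean runs over all `m` cohort
#' records. For a linear predictor this reduces to `0.2 * coef_i * mean(h_i)`.
#'
#' @param model an `ovr_model`.
#' @param cohort the full cohort the importance is referred to.
#' @param feature name of one of the model's input features.
#' @param schema a [cohort_schema()].
#' @return The mean impact value (oocytes per +/-10% perturbation).
#' @export
compute_miv <- function(model, cohort, feature, schema = cohort_schema()) {
  if (!feature %in% model$features)
    stop("feature '", feature, "' is not among the model inputs")
  enc <- encode_cohort(as.data.frame(cohort), schema)
  up <- dn <- enc
  up[[feature]] <- 1.1 * enc[[feature]]
  dn[[feature]] <- 0.9 * enc[[feature]]
  # a 10% bump may leave the observed range; that is intended (no re-clipping)
  mean(predict_encoded(model, up, warn_extrapolation = FALSE) -
       predict_encoded(model, dn, warn_extrapolation = FALSE))
}

#' Normalize a mean-impact-value vector
#'
#' `nmiv = miv / max(abs(miv))`: signs are preserved and exactly one entry
#' attains absolute value 1. An all-zero MIV vector (a constant model) has no
#' defined normalization and raises an error.
#'
#' @param mivs numeric vector of mean impact values (may be named).
#' @return The normalized vector, same names.
#' @examples
#' normalize_miv(c(-2, 1, 4))  # -0.5, 0.25, 1.0
#' @export
normalize_miv <- function(mivs) {
  if (!length(mivs)) stop("empty MIV vector")
  mx <- max(abs(mivs))
  if (mx == 0)
    stop("degenerate importance: all mean impact values are zero (constant model)")
  mivs / mx
}

#' Rank features by normalized mean impact value
#'
#' Builds the importance table: features sorted by |NMIV| descending (ties
#' broken by schema order), paired with the univariate Pearson r from the
#' screening stage. Categorical features carry a sign note, since their NMIV
#' sign depends on the arbitrary integer encoding and has no definite
#' clinical meaning.
#'
#' @param nmivs named numeric vector from [normalize_miv()].
#' @param screen an `ovr_screen` covering the same features (extra screened
#'   features are ignored; missing ones are an error).
#' @param mivs optional named vector of raw MIVs to carry along.
#' @param schema a [cohort_schema()].
#' @return A data frame of class `ovr_importance`: `feature`, `miv`, `nmiv`,
#'   `rank`, `r`, `sign_note`.
#' @export
rank_features <- function(nmivs, screen, mivs = NULL,
                          schema = cohort_schema()) {
  feats <- names(nmivs)
  if (is.null(feats)) stop("nmivs must be a named vector")
  if (!all(feats %in% screen$feature))
    stop("screen results do not cover: ",
         paste(setdiff(feats, screen$feature), collapse = ", "))
  schema_pos <- match(feats, schema$features$name)
  ord <- order(-abs(nmivs), schema_pos)
  feats <- feats[ord]
  tab <- data.frame(
    feature = feats,
    miv = if (is.null(mivs)) NA_real_ else unname(mivs[feats]),
    nmiv = unname(nmivs[ord]),
    rank = seq_along(feats),
    r = screen$r[match(feats, screen$feature)],
    sign_note = ifelse(is_categorical(feats, schema),
                       "encoding-dependent sign", ""),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("ovr_importance", "data.frame")
  tab
}

#' Full perturbation-importance table for a trained model
#'
#' Convenience wrapper: computes the MIV of every model input over the
#' cohort, normalizes, and ranks against the screening correlations.
#'
#' @inheritParams compute_miv
#' @param screen an `ovr_screen` for the same cohort.
#' @return An `ovr_importance` table.
#' @examples
#' \donttest{
#' cfg <- default_generator_config(n = 300, seed = 3)
#' cohort <- generate_cohort(cfg)
#' scr <- pearson_screen(cohort)
#' fit <- train_ann(cohort, selected_features(scr), max_iter = 50, seed = 3)
#' feature_importance(fit, cohort, scr)
#' }
#' @export
feature_importance <- function(model, cohort, screen,
                               schema = cohort_schema()) {
  mivs <- vapply(model$features, function(f)
    compute_miv(model, cohort, f, schema), numeric(1))
  rank_features(normalize_miv(mivs), screen, mivs = mivs, schema = schema)
}

#' @export
print.ovr_importance <- function(x, ...) {
  cat("Perturbation-based feature importance (NMIV), ",
      nrow(x), " features\n", sep = "")
  df <- as.data.frame(x)
  df$miv <- round(df$miv, 4)
  df$nmiv <- round(df$nmiv, 3)
  df$r <- round(df$r, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Plot an importance table
#'
#' Horizontal bar chart of the normalized mean impact values in rank order,
#' with the univariate Pearson correlations overlaid as points, so the
#' model-based and correlation-based views of each feature can be compared
#' at a glance.
#'
#' @param x an `ovr_importance` table.
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot.ovr_importance <- function(x, ...) {
  tab <- x[rev(seq_len(nrow(x))), ]
  old <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(old))
  mid <- graphics::barplot(tab$nmiv, names.arg = tab$feature, horiz = TRUE,
                           las = 1, xlab = "normalized mean impact value",
                           xlim = range(c(-1, 1, tab$nmiv, tab$r)),
                           col = ifelse(tab$nmiv >= 0, "steelblue", "indianred"),
                           ...)
  graphics::points(tab$r, mid, pch = 19)
  graphics::abline(v = 0, lty = 2)
  graphics::legend("bottomright", legend = c("NMIV", "Pearson r"),
                   fill = c("grey", NA), border = c("black", NA),
                   pch = c(NA, 19), bty = "n")
  invisible(mid)
}
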