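# Univariate Pearson screening of candidate impact features.

#' Pearson correlation screen of candidate features
#'
#' Correlates each of the 13 candidate features with the number of oocytes
#' retrieved and selects those with a two-sided p-value below `alpha`.
#' Categorical features are integer-encoded (schema listing order) before
#' correlating, so their r values are encoding-dependent — a deliberate
#' fidelity to common clinical practice rather than a statistical
#' recommendation. No multiple-testing correction is applied.
#'
#' The p-value comes from the t transform `t = r * sqrt((m - 2) / (1 - r^2))`
#' on `m - 2` degrees of freedom, where `m` is the number of records.
#'
#' @param cohort a cohort data frame.
#' @param alpha significance level for selection (default 0.05).
#' @param schema a [cohort_schema()].
#' @return A data frame of class `ovr_screen`, one row per feature in schema
#'   order: `feature`, `r`, `p_value`, `selected`, `note` (flags
#'   zero-variance features, which are reported as not selected with `r = NA`).
#' @examples
#' cohort <- generate_cohort(default_generator_config(n = 300, seed = 7))
#' scr <- pearson_screen(cohort)
#' scr[scr$selected, "feature"]
#' @export
pearson_screen <- function(cohort, alpha = 0.05, schema = cohort_schema()) {
  m <- nrow(cohort)
  if (m < 3) stop("Pearson screening needs at least 3 records, got ", m)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  enc <- encode_cohort(cohort, schema)
  y <- enc[[schema$outcome]]
  feats <- schema$features$name
  r <- p <- rep(NA_real_, length(feats))
  note <- rep("", length(feats))
  for (i in seq_along(feats)) {
    x <- enc[[feats[i]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      note[i] <- "zero_variance"
      next
    }
    ri <- stats::cor(x, y)
    r[i] <- ri
    if (abs(ri) >= 1) {
      p[i] <- 0
    } else {
      tstat <- ri * sqrt((m - 2) / (1 - ri^2))
      p[i] <- 2 * stats::pt(-abs(tstat), df = m - 2)
    }
  }
  res <- data.frame(feature = feats, r = r, p_value = p,
                    selected = !is.na(p) & p < alpha,
                    note = note, stringsAsFactors = FALSE)
  attr(res, "alpha") <- alpha
  attr(res, "n") <- m
  class(res) <- c("ovr_screen", "data.frame")
  res
}

#' Names of the selected impact features
#'
#' @param screen an `ovr_screen` result.
#' @return Character vector of the features with `p < alpha`, in schema order.
#' @export
selected_features <- function(screen) {
  stopifnot(inherits(screen, "ovr_screen"))
  screen$feature[screen$selected]
}

#' @export
print.ovr_screen <- function(x, ...) {
  cat("Pearson feature screen (alpha =", attr(x, "alpha"),
      ", n =", attr(x, "n"), "):",
      sum(x$selected), "of", nrow(x), "features selected\n")
  df <- as.data.frame(x)
  df$r <- round(df$r, 3)
  df$p_value <- signif(df$p_value, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
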