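# Cohort feature schema: 13 candidate impact features + the outcome.
# Continuous bounds are the observed clinical ranges used for truncation and
# validation; categorical levels are listed in their conventional clinical order,
# which also fixes the integer encoding (1-based, in listing order).

.FEATURES <- data.frame(
  name = c("age", "infertility_type", "infertility_duration", "bmi", "afc",
           "bfsh", "basal_e2", "amh", "infertility_cause",
           "therapeutic_regimen", "days_gn", "dosage_gn", "e2_hcg"),
  kind = c("continuous", "categorical", "continuous", "continuous", "continuous",
           "continuous", "continuous", "continuous", "categorical",
           "categorical", "continuous", "continuous", "continuous"),
  lower = c(21, NA, 0, 15, 2, 0.97, 3.92, 0.1, NA, NA, 0, 0, 57.41),
  upper = c(50, NA, 22, 36.2, 65, 151.65, 5086.19, 23, NA, NA, 55, 6262.5, 19432.6),
  stringsAsFactors = FALSE
)

.CAT_LEVELS <- list(
  infertility_type = c("primary", "secondary"),
  infertility_cause = c("pelvic_tubal", "pcos", "dor",
                        "endometriosis_uterine", "multiple", "other"),
  therapeutic_regimen = c("long", "super_long", "antagonist", "ppos", "other")
)

.OUTCOME <- "oocytes_retrieved"

#' Cohort feature schema
#'
#' Describes the 13 candidate impact features of a controlled ovarian
#' stimulation (COS) cohort and the outcome column (number of oocytes
#' retrieved). Ten features are continuous (with clinical truncation bounds)
#' and three are categorical: infertility type (2 levels), infertility cause
#' (6 levels) and therapeutic regimen (5 levels). Categorical levels are
#' integer-encoded 1..k in listing order wherever a numeric representation is
#' needed (screening, model inputs, perturbation importance).
#'
#' @return An object of class `ovr_schema`: a list with elements
#'   `features` (data frame of name/kind/lower/upper), `levels` (named list of
#'   categorical level labels), `outcome` (outcome column name) and
#'   `outcome_bounds` (admissible integer range of the oocyte count).
#' @examples
#' sch <- cohort_schema()
#' sch$features$name
#' @export
cohort_schema <- function() {
  structure(
    list(features = .FEATURES,
         levels = .CAT_LEVELS,
         outcome = .OUTCOME,
         outcome_bounds = c(0, 29)),
    class = "ovr_schema"
  )
}

#' @export
print.ovr_schema <- function(x, ...) {
  cat("Cohort schema:", nrow(x$features), "candidate features +",
      x$outcome, "\n")
  n_cat <- sum(x$features$kind == "categorical")
  cat("  continuous:", sum(x$features$kind == "continuous"),
      " categorical:", n_cat, "\n")
  cat("  outcome bounds: [", x$outcome_bounds[1], ",", x$outcome_bounds[2],
      "] (integer)\n")
  invisible(x)
}

feature_names <- function(schema = cohort_schema()) schema$features$name

is_categorical <- function(feature, schema = cohort_schema()) {
  kind <- schema$features$kind[match(feature, schema$features$name)]
  !is.na(kind) & kind == "categorical"
}

#' Integer-encode the categorical columns of a cohort
#'
#' Replaces each categorical label by its 1-based position in the schema's
#' level listing, leaving continuous columns untouched. This is the numeric
#' representation used by the Pearson screen, the regression models, and the
#' perturbation-based importance statistic; results involving categorical
#' features are therefore encoding-dependent.
#'
#' @param cohort a cohort data frame (see [generate_cohort()] / [read_cohort()]).
#' @param schema a [cohort_schema()].
#' @return A data frame with the same columns, all numeric.
#' @export
encode_cohort <- function(cohort, schema = cohort_schema()) {
  out <- cohort
  for (f in names(schema$levels)) {
    if (!f %in% names(out)) next
    if (is.numeric(out[[f]])) next
    code <- match(as.character(out[[f]]), schema$levels[[f]])
    if (anyNA(code)) {
      bad <- which(is.na(code))[1]
      stop(sprintf("unknown level '%s' in column '%s' (row %d)",
                   as.character(out[[f]])[bad], f, bad))
    }
    out[[f]] <- as.numeric(code)
  }
  out
}

#' Validate a cohort table against the schema
#'
#' Checks column presence, absence of missing values, truncation bounds of the
#' continuous features, membership of categorical labels, and that the outcome
#' is an integer count within its admissible range.
#'
#' @inheritParams encode_cohort
#' @return `cohort`, invisibly, if valid; otherwise an error naming the first
#'   offending row and column.
#' @export
validate_cohort <- function(cohort, schema = cohort_schema()) {
  needed <- c(schema$features$name, schema$outcome)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(cohort), needed)
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  for (cn in needed) {
    if (anyNA(cohort[[cn]]))
      stop(sprintf("missing value in column '%s' (row %d)",
                   cn, which(is.na(cohort[[cn]]))[1]))
  }
  ft <- schema$features
  for (i in seq_len(nrow(ft))) {
    f <- ft$name[i]
    v <- cohort[[f]]
    if (ft$kind[i] == "continuous") {
      if (!is.numeric(v))
        stop(sprintf("column '%s' must be numeric", f))
      bad <- which(v < ft$lower[i] | v > ft$upper[i])
      if (length(bad))
        stop(sprintf("value %g in column '%s' (row %d) outside bounds [%g, %g]",
                     v[bad[1]], f, bad[1], ft$lower[i], ft$upper[i]))
    } else {
      lv <- schema$levels[[f]]
      bad <- which(!(as.character(v) %in% lv))
      if (length(bad))
        stop(sprintf("unknown level '%s' in column '%s' (row %d)",
                     as.character(v)[bad[1]], f, bad[1]))
    }
  }
  y <- cohort[[schema$outcome]]
  if (!is.numeric(y)) stop("outcome must be numeric")
  if (any(y != round(y)))
    stop(sprintf("outcome must be an integer count (row %d)",
                 which(y != round(y))[1]))
  ob <- schema$outcome_bounds
  bad <- which(y < ob[1] | y > ob[2])
  if (length(bad))
    stop(sprintf("outcome %g (row %d) outside bounds [%d, %d]",
                 y[bad[1]], bad[1], ob[1], ob[2]))
  invisible(cohort)
}
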