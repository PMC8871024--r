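# Common predictor contract for the trained regressors: a model holds the
# feature list, a min-max scaler fitted on training data, the fitted
# parameters, and a deterministic predict function on raw (label-valued)
# records. A plain linear model kind is included as a transparent reference
# predictor for testing and illustration of the importance statistic.

# ---- min-max scaler -----------------------------------------------------

fit_minmax <- function(X) {
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  rng <- maxs - mins
  rng[rng == 0] <- 1  # constant columns map to 0
  list(min = mins, range = rng)
}

apply_minmax <- function(X, scaler, warn_extrapolation = TRUE) {
  Xs <- sweep(sweep(X, 2, scaler$min), 2, scaler$range, "/")
  if (warn_extrapolation && (any(Xs < -1e-9) || any(Xs > 1 + 1e-9)))
    warning("record values outside the model's training range; ",
            "prediction is an extrapolation", call. = FALSE)
  Xs
}

# ---- model object -------------------------------------------------------

new_ovr_model <- function(kind, features, scaler, fit, hyperparams,
                          diagnostics = list()) {
  structure(
    list(kind = kind, features = features, scaler = scaler, fit = fit,
         hyperparams = hyperparams, diagnostics = diagnostics, version = 1L),
    class = "ovr_model"
  )
}

#' Reference linear predictor
#'
#' A transparent predictor `F(h) = intercept + sum(coefs * h)` on
#' integer-encoded features, satisfying the same predict contract as the
#' trained models. Its mean impact value has the closed form
#' `0.2 * coef_i * mean(h_i)`, which makes it the natural oracle for the
#' perturbation-importance statistic.
#'
#' @param coefs named numeric vector of slopes (names are feature names).
#' @param intercept intercept term (oocytes).
#' @return An `ovr_model` of kind `"linear"`.
#' @export
linear_model <- function(coefs, intercept = 0) {
  stopifnot(!is.null(names(coefs)), all(names(coefs) != ""))
  new_ovr_model("linear", names(coefs),
                scaler = NULL,
                fit = list(coefs = coefs, intercept = intercept),
                hyperparams = list())
}

# numeric-matrix predict path shared by predict() and the importance code
predict_encoded <- function(model, M, warn_extrapolation = TRUE) {
  M <- as.matrix(M[, model$features, drop = FALSE])
  if (model$kind == "linear") {
    return(as.numeric(model$fit$intercept + M %*% model$fit$coefs))
  }
  Xs <- apply_minmax(M, model$scaler, warn_extrapolation)
  if (model$kind == "ann") {
    ann_forward(model$fit, Xs)$yhat
  } else if (model$kind == "svr") {
    svr_decision(model$fit, Xs)
  } else {
    stop("unknown model kind: ", model$kind)
  }
}

#' Predict the number of oocytes retrieved
#'
#' Applies the model's stored scaler and fitted function to new records. The
#' output is a finite real number, neither rounded nor clipped. Records with
#' feature values outside the scaler's training range trigger an
#' extrapolation warning, not an error.
#'
#' @param object an `ovr_model`.
#' @param newdata a data frame supplying all model features (categorical
#'   columns may be labels, which are integer-encoded first).
#' @param ... unused.
#' @return Numeric vector of predicted oocyte counts.
#' @export
predict.ovr_model <- function(object, newdata, ...) {
  enc <- encode_cohort(as.data.frame(newdata), cohort_schema())
  miss <- setdiff(object$features, names(enc))
  if (length(miss))
    stop("record is missing model feature(s): ", paste(miss, collapse = ", "))
  for (f in object$features) {
    if (!is.numeric(enc[[f]]) || anyNA(enc[[f]]))
      stop("feature '", f, "' must be numeric and non-missing")
  }
  out <- predict_encoded(object, enc)
  if (any(!is.finite(out))) stop("model produced a non-finite prediction")
  out
}

#' @export
print.ovr_model <- function(x, ...) {
  cat("Oocyte-count regression model [", x$kind, "], ",
      length(x$features), " input features\n", sep = "")
  d <- x$diagnostics
  if (!is.null(d$train_rmse))
    cat("  training RMSE:", round(d$train_rmse, 3), "oocytes\n")
  if (!is.null(d$iterations)) cat("  iterations:", d$iterations, "\n")
  invisible(x)
}

#' Select the best model from matched evaluation reports
#'
#' Returns the model with the lowest RMSE; ties are broken by the higher
#' regression coefficient R, then by declaration order.
#'
#' @param models list of `ovr_model` objects.
#' @param reports list of evaluation reports from [evaluate_model()], same
#'   order as `models`.
#' @return The selected `ovr_model`, with attribute `"selected_index"`.
#' @export
select_model <- function(models, reports) {
  if (length(models) == 0) stop("no models to select from")
  if (length(models) != length(reports))
    stop("models and reports must match one-to-one")
  rmse <- vapply(reports, function(r) r$rmse, numeric(1))
  rc <- vapply(reports, function(r) ifelse(is.na(r$r_coef), -Inf, r$r_coef),
               numeric(1))
  ord <- order(rmse, -rc, seq_along(models))
  best <- models[[ord[1]]]
  attr(best, "selected_index") <- ord[1]
  best
}

# ---- serialization ------------------------------------------------------

#' Write a trained model to a versioned JSON file
#'
#' Serializes the model kind, feature list, scaler, hyperparameters,
#' diagnostics and fitted parameters (network weights, or support vectors and
#' dual coefficients) at full numeric precision.
#'
#' @param model an `ovr_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ovr_model"))
  payload <- unclass(model)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a trained model from JSON
#'
#' @param path a file written by [write_model()].
#' @return An `ovr_model` whose predictions are identical to the original's.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$kind) || is.null(p$version))
    stop("not a serialized ovaresp model: ", path)
  to_mat <- function(x) if (is.null(x)) NULL else as.matrix(x)
  if (p$kind == "ann") {
    p$fit$W1 <- to_mat(p$fit$W1); p$fit$W2 <- to_mat(p$fit$W2)
    p$fit$w3 <- as.numeric(p$fit$w3)
  } else if (p$kind == "svr") {
    p$fit$SV <- to_mat(p$fit$SV)
    p$fit$coefs <- as.numeric(p$fit$coefs)
  }
  if (!is.null(p$scaler)) {
    p$scaler$min <- stats::setNames(as.numeric(p$scaler$min), p$features)
    p$scaler$range <- stats::setNames(as.numeric(p$scaler$range), p$features)
  }
  structure(p, class = "ovr_model")
}

# ---- data split ---------------------------------------------------------

#' Train/validation/test split specification
#'
#' @param train,validation,test positive fractions summing to 1; the default
#'   reserves 70% for training and splits the remainder evenly.
#' @param seed shuffle seed.
#' @return An object of class `ovr_split`.
#' @export
split_spec <- function(train = 0.70, validation = 0.15, test = 0.15,
                       seed = 1) {
  fr <- c(train, validation, test)
  if (any(fr <= 0) || abs(sum(fr) - 1) > 1e-8)
    stop("split fractions must be positive and sum to 1")
  structure(list(train = train, validation = validation, test = test,
                 seed = as.integer(seed)), class = "ovr_split")
}

make_split <- function(n, split) {
  set.seed(split$seed)
  idx <- sample.int(n)
  n_tr <- round(split$train * n)
  n_va <- round(split$validation * n)
  list(train = sort(idx[seq_len(n_tr)]),
       validation = sort(idx[n_tr + seq_len(n_va)]),
       test = sort(idx[(n_tr + n_va + 1):n]))
}
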