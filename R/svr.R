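# Epsilon-insensitive support vector regression with a Gaussian kernel,
# epsilon = 0.5 on the raw oocyte-count axis. Hyperparameters (kernel scale
# and box constraint) are selected by 10-fold cross-validated RMSE over a
# fixed grid; the underlying quadratic program is solved by libsvm's SMO
# (via e1071). The trained model is stored in dual form (support vectors,
# dual coefficients, offset) so that prediction and serialization are
# self-contained.

svr_decision <- function(fit, Xs) {
  SV <- fit$SV
  d2 <- outer(rowSums(Xs^2), rowSums(SV^2), "+") - 2 * Xs %*% t(SV)
  d2[d2 < 0] <- 0
  K <- exp(-fit$gamma * d2)
  as.numeric(K %*% fit$coefs) - fit$rho
}

#' Train the support-vector oocyte-count regressor
#'
#' Epsilon-insensitive regression with a Gaussian (radial) kernel on
#' min-max-scaled inputs, `epsilon = 0.5` oocytes on the response. The kernel
#' scale sigma is searched over multiples of the median pairwise distance of
#' the scaled training records, and the box constraint C over a decade grid;
#' the pair with the lowest 10-fold cross-validated RMSE wins (ties go to the
#' earlier grid entry). The final model is refit on all records with the
#' chosen pair; `gamma = 1 / (2 sigma^2)`.
#'
#' @inheritParams train_ann
#' @param epsilon half-width of the insensitivity tube, in oocytes.
#' @param scale_multipliers grid of kernel-scale multiples of the median
#'   pairwise distance.
#' @param costs grid of box-constraint values.
#' @param folds number of cross-validation folds.
#' @param seed seed for the fold assignment (and the median-distance
#'   subsample on large cohorts).
#' @param tolerance termination tolerance of the SMO solver.
#' @return An `ovr_model` of kind `"svr"` with the cross-validation table in
#'   its diagnostics.
#' @export
train_svr <- function(cohort, features = NULL, epsilon = 0.5,
                      scale_multipliers = c(0.25, 0.5, 1, 2, 4),
                      costs = c(0.1, 1, 10, 100), folds = 10, seed = 1,
                      tolerance = 0.001, schema = cohort_schema()) {
  if (is.null(features)) features <- schema$features$name
  miss <- setdiff(features, names(cohort))
  if (length(miss))
    stop("cohort is missing model feature(s): ", paste(miss, collapse = ", "))
  n <- nrow(cohort)
  if (n < 50) stop("need at least 50 records to train the regressor, got ", n)
  if (!length(scale_multipliers) || !length(costs))
    stop("empty hyperparameter search grid")

  enc <- encode_cohort(cohort, schema)
  M <- as.matrix(enc[, features, drop = FALSE])
  y <- enc[[schema$outcome]]
  scaler <- fit_minmax(M)
  Xs <- apply_minmax(M, scaler, FALSE)

  set.seed(as.integer(seed))
  sub <- if (n > 400) sort(sample.int(n, 400)) else seq_len(n)
  med <- stats::median(stats::dist(Xs[sub, , drop = FALSE]))
  if (!is.finite(med) || med <= 0)
    stop("degenerate kernel: median pairwise distance is zero")
  fold_id <- sample(rep(seq_len(folds), length.out = n))

  grid <- expand.grid(scale_mult = scale_multipliers, cost = costs,
                      KEEP.OUT.ATTRS = FALSE)
  grid$gamma <- 1 / (2 * (grid$scale_mult * med)^2)
  grid$cv_rmse <- NA_real_
  for (g in seq_len(nrow(grid))) {
    sse <- 0
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      m <- e1071::svm(x = Xs[tr, , drop = FALSE], y = y[tr],
                      type = "eps-regression", kernel = "radial",
                      gamma = grid$gamma[g], cost = grid$cost[g],
                      epsilon = epsilon, scale = FALSE, tolerance = tolerance)
      pred <- stats::predict(m, Xs[!tr, , drop = FALSE])
      sse <- sse + sum((pred - y[!tr])^2)
    }
    grid$cv_rmse[g] <- sqrt(sse / n)
  }
  best <- which.min(grid$cv_rmse)

  m <- e1071::svm(x = Xs, y = y, type = "eps-regression", kernel = "radial",
                  gamma = grid$gamma[best], cost = grid$cost[best],
                  epsilon = epsilon, scale = FALSE, tolerance = tolerance)
  fit <- list(SV = unname(as.matrix(m$SV)),
              coefs = as.numeric(m$coefs),
              rho = as.numeric(m$rho),
              gamma = grid$gamma[best])
  train_rmse <- sqrt(mean((svr_decision(fit, Xs) - y)^2))

  new_ovr_model(
    kind = "svr", features = features, scaler = scaler, fit = fit,
    hyperparams = list(epsilon = epsilon, cost = grid$cost[best],
                       gamma = grid$gamma[best],
                       kernel_scale = grid$scale_mult[best] * med,
                       folds = folds),
    diagnostics = list(train_rmse = train_rmse, cv_grid = grid,
                       n_sv = nrow(fit$SV), seed = as.integer(seed))
  )
}
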