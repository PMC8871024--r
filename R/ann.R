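# Feed-forward network (11 -> 4 -> 6 -> 1, sigmoid hidden units, linear
# output) trained by Levenberg-Marquardt with an L2 weight penalty and
# validation-based early stopping. The Jacobian of the residual vector is
# computed analytically by backpropagation, vectorized over records; the LM
# damping parameter mu starts at 0.01, scales the diagonal of the
# Gauss-Newton Hessian (Marquardt scaling), and is divided/multiplied by 10
# on accepted/rejected steps.

sigmoid <- function(x) 1 / (1 + exp(-x))

ann_dims <- function(p, hidden) {
  h1 <- hidden[1]; h2 <- hidden[2]
  list(p = p, h1 = h1, h2 = h2,
       n_par = h1 * p + h1 + h2 * h1 + h2 + h2 + 1)
}

ann_unpack <- function(theta, d) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(d$h1 * d$p)], d$h1, d$p); i <- i + d$h1 * d$p
  b1 <- theta[i + seq_len(d$h1)]; i <- i + d$h1
  W2 <- matrix(theta[i + seq_len(d$h2 * d$h1)], d$h2, d$h1); i <- i + d$h2 * d$h1
  b2 <- theta[i + seq_len(d$h2)]; i <- i + d$h2
  w3 <- theta[i + seq_len(d$h2)]; i <- i + d$h2
  b3 <- theta[i + 1]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, w3 = w3, b3 = b3)
}

ann_pack <- function(fit) {
  c(as.numeric(fit$W1), fit$b1, as.numeric(fit$W2), fit$b2, fit$w3, fit$b3)
}

# mask of entries subject to the L2 penalty (weights yes, biases no)
ann_l2_mask <- function(d) {
  c(rep(1, d$h1 * d$p), rep(0, d$h1),
    rep(1, d$h2 * d$h1), rep(0, d$h2),
    rep(1, d$h2), 0)
}

ann_forward <- function(fit, X) {
  A1 <- sigmoid(sweep(X %*% t(fit$W1), 2, fit$b1, "+"))
  A2 <- sigmoid(sweep(A1 %*% t(fit$W2), 2, fit$b2, "+"))
  yhat <- as.numeric(A2 %*% fit$w3 + fit$b3)
  list(A1 = A1, A2 = A2, yhat = yhat)
}

# Jacobian d yhat / d theta, one row per record
ann_jacobian <- function(fit, X, fw) {
  n <- nrow(X)
  D2 <- fw$A2 * (1 - fw$A2) * matrix(fit$w3, n, length(fit$w3), byrow = TRUE)
  D1 <- (D2 %*% fit$W2) * (fw$A1 * (1 - fw$A1))
  J_W1 <- do.call(cbind, lapply(seq_len(ncol(X)), function(j) D1 * X[, j]))
  J_W2 <- do.call(cbind, lapply(seq_len(ncol(fw$A1)), function(j) D2 * fw$A1[, j]))
  cbind(J_W1, D1, J_W2, D2, fw$A2, rep(1, n))
}

#' Train the neural-network oocyte-count regressor
#'
#' Fits a feed-forward network with two sigmoid hidden layers (4 and 6
#' neurons) and a linear output by Levenberg-Marquardt on min-max-scaled
#' inputs, with an L2 penalty on the weights. 70% of the records (by default)
#' are used for training; training stops on validation-error early stopping
#' (after `patience` consecutive increases, restoring the best weights) or at
#' `max_iter` iterations.
#'
#' @param cohort a cohort data frame restricted conceptually to the selected
#'   impact features (pass them via `features`).
#' @param features character vector of model input features (the screened
#'   set); defaults to all 13 candidates.
#' @param split an [split_spec()]; the scaler and the LM objective use the
#'   training rows only.
#' @param hidden hidden layer sizes, default `c(4, 6)`.
#' @param l2 L2 penalty on the weights (scaled-loss convention), default 1e-4.
#' @param max_iter maximum LM iterations, default 1000.
#' @param mu_init initial LM damping parameter, default 0.01.
#' @param patience consecutive validation-error increases tolerated before
#'   stopping, default 6.
#' @param seed seed for weight initialization (and, through `split`, the data
#'   shuffle); the fit is deterministic given cohort, seed and hyperparameters.
#' @param schema a [cohort_schema()].
#' @return An `ovr_model` of kind `"ann"` with training diagnostics
#'   (`train_rmse`, `val_rmse`, `iterations`, `seed`, split indices).
#' @export
train_ann <- function(cohort, features = NULL, split = split_spec(),
                      hidden = c(4, 6), l2 = 1e-4, max_iter = 1000,
                      mu_init = 0.01, patience = 6, seed = 1,
                      schema = cohort_schema()) {
  if (is.null(features)) features <- schema$features$name
  miss <- setdiff(features, names(cohort))
  if (length(miss))
    stop("cohort is missing model feature(s): ", paste(miss, collapse = ", "))
  n <- nrow(cohort)
  if (n < 50) stop("need at least 50 records to train the network, got ", n)

  enc <- encode_cohort(cohort, schema)
  M <- as.matrix(enc[, features, drop = FALSE])
  y <- enc[[schema$outcome]]
  idx <- make_split(n, split)
  scaler <- fit_minmax(M[idx$train, , drop = FALSE])
  Xtr <- apply_minmax(M[idx$train, , drop = FALSE], scaler, FALSE)
  ytr <- y[idx$train]
  Xva <- apply_minmax(M[idx$validation, , drop = FALSE], scaler, FALSE)
  yva <- y[idx$validation]
  n_tr <- nrow(Xtr)

  d <- ann_dims(ncol(M), hidden)
  set.seed(as.integer(seed))
  glorot <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  }
  fit <- list(W1 = glorot(d$h1, d$p), b1 = rep(0, d$h1),
              W2 = glorot(d$h2, d$h1), b2 = rep(0, d$h2),
              w3 = stats::runif(d$h2, -1, 1) * sqrt(6 / (d$h2 + 1)),
              b3 = mean(ytr))
  theta <- ann_pack(fit)
  mask <- ann_l2_mask(d)

  objective <- function(theta) {
    fw <- ann_forward(ann_unpack(theta, d), Xtr)
    r <- fw$yhat - ytr
    list(value = mean(r^2) + l2 * sum(mask * theta^2), resid = r, fw = fw)
  }

  cur <- objective(theta)
  if (!is.finite(cur$value)) stop("training diverged: non-finite loss")
  mu <- mu_init
  best_val <- Inf
  best_theta <- theta
  val_increases <- 0
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    fit_cur <- ann_unpack(theta, d)
    J <- ann_jacobian(fit_cur, Xtr, cur$fw)
    g <- 2 * crossprod(J, cur$resid)[, 1] / n_tr + 2 * l2 * mask * theta
    H <- 2 * crossprod(J) / n_tr + diag(2 * l2 * mask, d$n_par)
    if (sqrt(sum(g^2)) < 1e-10) break
    accepted <- FALSE
    dH <- pmax(diag(H), 1e-10)   # Marquardt scaling: damp along the curvature
    for (k in 1:30) {
      step <- tryCatch(
        solve(H + mu * diag(dH, d$n_par), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + as.numeric(step)
        new <- objective(cand)
        if (is.finite(new$value) && new$value < cur$value) {
          theta <- cand
          cur <- new
          mu <- max(mu / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
      if (mu > 1e12) break
    }
    if (!accepted) break
    if (length(yva)) {
      val_rmse <- sqrt(mean((ann_forward(ann_unpack(theta, d), Xva)$yhat - yva)^2))
      if (val_rmse < best_val) {
        best_val <- val_rmse
        best_theta <- theta
        val_increases <- 0
      } else {
        val_increases <- val_increases + 1
        if (val_increases >= patience) break
      }
    } else {
      best_theta <- theta
    }
  }
  theta <- best_theta
  fit_final <- ann_unpack(theta, d)
  train_rmse <- sqrt(mean((ann_forward(fit_final, Xtr)$yhat - ytr)^2))
  val_rmse <- if (length(yva))
    sqrt(mean((ann_forward(fit_final, Xva)$yhat - yva)^2)) else NA_real_

  new_ovr_model(
    kind = "ann", features = features, scaler = scaler, fit = fit_final,
    hyperparams = list(hidden = hidden, l2 = l2, max_iter = max_iter,
                       mu_init = mu_init, patience = patience),
    diagnostics = list(train_rmse = train_rmse, val_rmse = val_rmse,
                       iterations = iter, seed = as.integer(seed),
                       split = idx)
  )
}
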