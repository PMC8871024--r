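test_that("the network recovers a noiseless structural function", {
  ov <- linear_cohort_overrides(noise_sd = 0)
  co <- small_cohort(n = 800, seed = 21, overrides = ov)
  # near-zero validation noise makes early stopping jittery, so give it slack
  fit <- train_ann(co, seed = 21, split = split_spec(seed = 21),
                   patience = 30)
  # the only irreducible error left is the integer rounding of the outcome
  expect_lt(fit$diagnostics$train_rmse, 0.5)
  ev <- evaluate_model(fit, co)
  expect_gt(ev$r_coef, 0.99)
})

test_that("a constant outcome is fit to the constant", {
  co <- small_cohort(n = 120, seed = 3)
  co$oocytes_retrieved <- 10
  fit <- train_ann(co, seed = 3)
  pred <- suppressWarnings(predict(fit, co))
  expect_true(all(abs(pred - 10) < 0.1))
})

test_that("training is deterministic given cohort, seed and hyperparameters", {
  co <- small_cohort(n = 150, seed = 5)
  f1 <- train_ann(co, seed = 11)
  f2 <- train_ann(co, seed = 11)
  expect_identical(f1$fit, f2$fit)
  expect_identical(predict(f1, co[7, ]), predict(f2, co[7, ]))
  f3 <- train_ann(co, seed = 12)
  expect_false(identical(f1$fit, f3$fit))
})

test_that("predictions are invariant to affine rescaling of a raw input", {
  co <- small_cohort(n = 150, seed = 5)
  fit1 <- train_ann(co, seed = 2)
  co2 <- co
  co2$dosage_gn <- co2$dosage_gn * 3 + 500   # different units
  fit2 <- train_ann(co2, seed = 2)
  expect_equal(suppressWarnings(predict(fit1, co)),
               suppressWarnings(predict(fit2, co2)), tolerance = 1e-8)
})

test_that("the scaler maps training features into the unit interval", {
  co <- small_cohort(n = 150, seed = 5)
  fit <- train_ann(co, seed = 2)
  enc <- encode_cohort(co)
  tr <- fit$diagnostics$split$train
  M <- as.matrix(enc[tr, fit$features])
  Xs <- sweep(sweep(M, 2, fit$scaler$min), 2, fit$scaler$range, "/")
  expect_gte(min(Xs), 0)
  expect_lte(max(Xs), 1)
})

test_that("a stronger L2 penalty never reduces the training error", {
  co <- small_cohort(n = 200, seed = 14)
  rmse <- vapply(c(1e-4, 1e-2, 1), function(lam) {
    train_ann(co, l2 = lam, max_iter = 300, patience = 300,
              seed = 14)$diagnostics$train_rmse
  }, numeric(1))
  expect_true(all(diff(rmse) >= -1e-6))
})

test_that("the recovered function is monotone in a positive-effect feature", {
  ov <- linear_cohort_overrides(noise_sd = 0)
  co <- small_cohort(n = 400, seed = 23, overrides = ov)
  fit <- train_ann(co, seed = 23, split = split_spec(seed = 23))
  base <- co[1:100, ]
  bumped <- base
  bumped$afc <- pmin(base$afc * 1.3, 65)
  d <- suppressWarnings(predict(fit, bumped) - predict(fit, base))
  expect_gte(mean(d > 0), 0.95)
})

test_that("prediction contract: schema errors, extrapolation warnings, finiteness", {
  co <- small_cohort(n = 120, seed = 5)
  fit <- train_ann(co, seed = 5)
  rec <- co[3, ]
  expect_error(predict(fit, rec[, -which(names(rec) == "afc")]),
               "missing model feature")
  far <- rec
  far$afc <- 65   # beyond this training sample's observed range
  expect_warning(predict(fit, far), "extrapolation")
  expect_true(is.finite(suppressWarnings(predict(fit, far))))
  expect_error(train_ann(co[1:30, ], seed = 1), "at least 50")
})
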