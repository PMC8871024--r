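test_that("a feature identical to the outcome screens with r = 1 and p ~ 0", {
  co <- small_cohort(n = 60, seed = 4)
  co$infertility_duration <- as.numeric(co$oocytes_retrieved)
  scr <- suppressWarnings(pearson_screen(co))
  row <- scr[scr$feature == "infertility_duration", ]
  expect_equal(row$r, 1)
  expect_lt(row$p_value, 1e-12)
  expect_true(row$selected)
})

test_that("r and p match the closed-form Pearson/t computation on a toy table", {
  h <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  co <- small_cohort(n = 5, seed = 4)
  co$afc <- h + 10           # affine shift keeps values in bounds
  co$oocytes_retrieved <- y
  scr <- pearson_screen(co)
  row <- scr[scr$feature == "afc", ]
  # independent arithmetic, straight from the definitions
  m <- 5
  r_exp <- sum((h - mean(h)) * (y - mean(y))) /
    sqrt(sum((h - mean(h))^2) * sum((y - mean(y))^2))
  t_exp <- r_exp * sqrt((m - 2) / (1 - r_exp^2))
  p_exp <- 2 * stats::pt(-abs(t_exp), m - 2)
  expect_equal(row$r, r_exp, tolerance = 1e-12)
  expect_equal(row$p_value, p_exp, tolerance = 1e-12)
  # and against R's own reference implementation
  ct <- stats::cor.test(h, y)
  expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(row$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("r is invariant under affine rescaling of a continuous feature", {
  co <- small_cohort(n = 150, seed = 6)
  scr1 <- pearson_screen(co)
  co2 <- co
  co2$dosage_gn <- co2$dosage_gn / 2 + 100
  scr2 <- pearson_screen(co2)
  expect_equal(scr1$r[scr1$feature == "dosage_gn"],
               scr2$r[scr2$feature == "dosage_gn"], tolerance = 1e-12)
})

test_that("zero-variance features are flagged and not selected", {
  co <- small_cohort(n = 50, seed = 2)
  co$bmi <- 22
  scr <- pearson_screen(co)
  row <- scr[scr$feature == "bmi", ]
  expect_true(is.na(row$r))
  expect_false(row$selected)
  expect_equal(row$note, "zero_variance")
})

test_that("the analytic p agrees with a permutation p-value on a small cohort", {
  co <- small_cohort(n = 20, seed = 31)
  e <- encode_cohort(co)
  x <- e$afc
  y <- e$oocytes_retrieved
  scr <- pearson_screen(co)
  p_analytic <- scr$p_value[scr$feature == "afc"]
  r_obs <- abs(stats::cor(x, y))
  set.seed(99)
  B <- 4000
  r_perm <- replicate(B, abs(stats::cor(x, sample(y))))
  p_perm <- (1 + sum(r_perm >= r_obs)) / (B + 1)
  se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_analytic - p_perm), max(3 * se, 0.01))
})

test_that("selection frequency of a null feature is controlled at alpha", {
  # permuting the outcome makes every feature null by exchangeability;
  # BMI's selection frequency must then sit near alpha = 0.05
  co <- small_cohort(n = 30, seed = 13)
  set.seed(7)
  hits <- replicate(1000, {
    co$oocytes_retrieved <- sample(co$oocytes_retrieved)
    scr <- pearson_screen(co)
    scr$selected[scr$feature == "bmi"]
  })
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("degenerate inputs are rejected", {
  co <- small_cohort(n = 50, seed = 2)
  expect_error(pearson_screen(co[1:2, ]), "at least 3")
  expect_error(pearson_screen(co, alpha = 0), "alpha")
})

test_that("selected_features returns the sub-alpha features in schema order", {
  co <- small_cohort(n = 1000, seed = 17)
  scr <- pearson_screen(co)
  feats <- selected_features(scr)
  expect_true(all(feats %in% cohort_schema()$features$name))
  expect_identical(feats, scr$feature[scr$selected])
  expect_identical(selected_features(pearson_screen(co, alpha = 1)),
                   cohort_schema()$features$name)
})
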