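test_that("MIV of a linear model matches the closed form 0.2 * beta * mean(h)", {
  sch <- cohort_schema()
  set.seed(101)
  for (rep in 1:20) {
    co <- small_cohort(n = 50, seed = rep)
    enc <- encode_cohort(co)
    feats <- sample(sch$features$name, sample(3:8, 1))
    beta <- stats::setNames(stats::rnorm(length(feats), 0, 2), feats)
    model <- linear_model(beta, intercept = stats::rnorm(1, 10, 3))
    for (f in feats) {
      expected <- 0.2 * beta[[f]] * mean(enc[[f]])
      expect_lt(abs(compute_miv(model, co, f) - expected), 1e-9)
    }
  }
})

test_that("a constant model has zero MIV everywhere and no valid normalization", {
  co <- small_cohort(n = 40, seed = 2)
  model <- linear_model(c(afc = 0, age = 0), intercept = 11)
  mivs <- vapply(c("afc", "age"), function(f) compute_miv(model, co, f),
                 numeric(1))
  expect_equal(unname(mivs), c(0, 0))
  expect_error(normalize_miv(mivs), "degenerate")
})

test_that("a feature observed at zero has zero MIV", {
  co <- small_cohort(n = 40, seed = 2)
  co$dosage_gn <- 0
  model <- linear_model(c(dosage_gn = 3, afc = 1))
  expect_equal(compute_miv(model, co, "dosage_gn"), 0)
})

test_that("normalization preserves signs, is scale-free and peaks at exactly 1", {
  expect_equal(normalize_miv(c(-2, 1, 4)), c(-0.5, 0.25, 1))
  v <- c(a = -3.2, b = 0.7, c = 1.1)
  expect_equal(normalize_miv(v), normalize_miv(17.3 * v))
  set.seed(5)
  for (i in 1:25) {
    x <- stats::rnorm(sample(2:12, 1))
    nm <- normalize_miv(x)
    expect_identical(max(abs(nm)), 1)
    expect_equal(sum(abs(nm) == 1), 1L)
    expect_equal(sign(nm), sign(x))
  }
})

make_screen <- function(feats, r = NULL) {
  structure(
    data.frame(feature = feats,
               r = if (is.null(r)) stats::runif(length(feats), -1, 1) else r,
               p_value = 0.01, selected = TRUE, note = "",
               stringsAsFactors = FALSE),
    class = c("ovr_screen", "data.frame"), alpha = 0.05, n = 100)
}

test_that("ranking sorts by |NMIV|, breaks ties by schema order, flags categoricals", {
  nm <- c(afc = 1, age = -0.5, therapeutic_regimen = 0.5, bfsh = 0.1)
  tab <- rank_features(nm, make_screen(names(nm)))
  expect_equal(tab$feature, c("afc", "age", "therapeutic_regimen", "bfsh"))
  expect_equal(tab$rank, 1:4)     # age precedes regimen in the schema
  expect_equal(tab$sign_note[tab$feature == "therapeutic_regimen"],
               "encoding-dependent sign")
  expect_equal(tab$sign_note[tab$feature == "afc"], "")
  single <- rank_features(normalize_miv(c(amh = -0.3)), make_screen("amh"))
  expect_equal(single$nmiv, -1)
  expect_equal(single$rank, 1L)
  expect_error(rank_features(c(zz = 1), make_screen("afc")), "cover")
})

test_that("a reference-style NMIV profile ranks reserve markers on top", {
  nm <- c(age = -0.354, infertility_type = 0.107, infertility_duration = -0.039,
          afc = 1.0, bfsh = -0.131, amh = 0.314, infertility_cause = 0.070,
          therapeutic_regimen = -0.241, days_gn = 0.234, dosage_gn = 0.219,
          e2_hcg = 0.951)
  tab <- rank_features(nm, make_screen(names(nm)))
  expect_equal(tab$feature,
               c("afc", "e2_hcg", "age", "amh", "therapeutic_regimen",
                 "days_gn", "dosage_gn", "bfsh", "infertility_type",
                 "infertility_cause", "infertility_duration"))
})

test_that("inert model inputs are suppressed in the trained importance", {
  # BMI and basal E2 enter the model (alpha = 1 keeps all 13 features) but
  # have no effect in the structural function. The x1.1/x0.9 perturbation
  # amplifies low-CV features (the impact scales with mean/sd), so BMI's
  # spurious importance is intrinsically noisier than basal E2's; the checks
  # reflect that asymmetry.
  n_rep <- 8L
  bmi <- be2 <- rank_bmi <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    co <- generate_cohort(default_generator_config(seed = 300 + s))
    scr <- pearson_screen(co, alpha = 1)
    fit <- train_ann(co, selected_features(scr), seed = s,
                     split = split_spec(seed = s))
    imp <- feature_importance(fit, co, scr)
    bmi[s] <- abs(imp$nmiv[imp$feature == "bmi"])
    be2[s] <- abs(imp$nmiv[imp$feature == "basal_e2"])
    rank_bmi[s] <- imp$rank[imp$feature == "bmi"]
  }
  expect_gte(sum(be2 < 0.15), n_rep - 1L)
  expect_gte(sum(bmi < 0.15), n_rep %/% 2)
  expect_true(all(bmi < 0.5))
  # an inert feature never outranks the dominant reserve markers
  expect_true(all(rank_bmi > 2))
})

test_that("importance errors on features outside the model", {
  co <- small_cohort(n = 40, seed = 2)
  model <- linear_model(c(afc = 1))
  expect_error(compute_miv(model, co, "bmi"), "not among the model inputs")
})
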