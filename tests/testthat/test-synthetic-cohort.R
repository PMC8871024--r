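test_that("identical config and seed give a bitwise-identical cohort", {
  cfg <- default_generator_config(n = 150, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a, c2))
})

test_that("continuous features respect their clinical truncation bounds", {
  co <- small_cohort(n = 2000, seed = 5)
  sch <- cohort_schema()
  ft <- sch$features
  for (i in which(ft$kind == "continuous")) {
    expect_gte(min(co[[ft$name[i]]]), ft$lower[i])
    expect_lte(max(co[[ft$name[i]]]), ft$upper[i])
  }
  y <- co[[sch$outcome]]
  expect_true(all(y == round(y)))
  expect_gte(min(y), 0)
  expect_lte(max(y), 29)
  expect_false(anyNA(co))
  expect_cohort_valid(co)
})

test_that("calibrated marginal means are recovered within sampling error", {
  # outcome and ovarian-reserve markers, checked over several seeds at the
  # calibrated cohort size; 3-standard-error tolerance per draw
  targets <- c(oocytes_retrieved = 11.18, afc = 19.60, amh = 3.15,
               age = 32.44, bmi = 22.27)
  hits <- 0L
  n_seeds <- 6L
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(default_generator_config(seed = 100 + s))
    ok <- vapply(names(targets), function(v) {
      se <- stats::sd(co[[v]]) / sqrt(nrow(co))
      abs(mean(co[[v]]) - targets[[v]]) <= 3 * se
    }, logical(1))
    hits <- hits + all(ok)
  }
  expect_gte(hits, n_seeds - 1L)
})

test_that("zero noise and zero effects give a constant outcome", {
  ov <- list(noise_sd = 0,
             features = list(
               age = list(weight = 0), infertility_duration = list(weight = 0),
               afc = list(weight = 0), bfsh = list(weight = 0),
               amh = list(weight = 0), days_gn = list(weight = 0),
               dosage_gn = list(weight = 0), e2_hcg = list(weight = 0),
               infertility_type = list(offsets = c(0, 0)),
               infertility_cause = list(offsets = rep(0, 6)),
               therapeutic_regimen = list(offsets = rep(0, 5))))
  co <- small_cohort(n = 100, seed = 2, overrides = ov)
  y <- co$oocytes_retrieved
  expect_equal(length(unique(y)), 1L)
  expect_equal(unique(y), round(default_generator_config(n = 100)$intercept))
})

test_that("configured effect signs appear in the empirical correlations", {
  co <- small_cohort(n = 5000, seed = 9)
  e <- encode_cohort(co)
  y <- e$oocytes_retrieved
  expect_gt(stats::cor(e$afc, y), 0)
  expect_lt(stats::cor(e$age, y), 0)
  expect_gt(stats::cor(e$e2_hcg, y), 0)
  expect_lt(stats::cor(e$bfsh, y), 0)
  # dose-by-indication confounding: marginal correlation of dosage negative
  # even though its structural effect is positive
  expect_lt(stats::cor(e$dosage_gn, y), 0)
})

test_that("inert features stay uncorrelated with the outcome", {
  ok <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(default_generator_config(seed = 200 + s))
    e <- encode_cohort(co)
    y <- e$oocytes_retrieved
    ok <- ok + (abs(stats::cor(e$bmi, y)) < 0.08 &&
                  abs(stats::cor(e$basal_e2, y)) < 0.08)
  }
  expect_gte(ok, round(0.9 * n_seeds))
})

test_that("invalid generator configurations are rejected", {
  expect_error(default_generator_config(n = 1), "at least 2")
  expect_error(default_generator_config(overrides = list(noise_sd = -1)),
               "noise_sd")
  expect_error(
    default_generator_config(overrides = list(
      features = list(infertility_type = list(counts = NULL,
                                              probs = c(0.7, 0.2))))),
    "sum to 1")
  expect_error(generate_cohort(structure(list(), class = "list")),
               "generator_config")
})

test_that("the structural mean is the generator's noiseless regression function", {
  ov <- linear_cohort_overrides(noise_sd = 0)
  cfg <- default_generator_config(n = 400, seed = 3, overrides = ov)
  co <- generate_cohort(cfg)
  g <- structural_mean(cfg, encode_cohort(co))
  expect_true(all(abs(co$oocytes_retrieved -
                        pmin(pmax(round(g), 0), 29)) == 0))
})
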