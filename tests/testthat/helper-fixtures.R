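# Shared fixtures: all cohorts are generated in code at test time.

small_cohort <- function(n = 200, seed = 1, overrides = list()) {
  generate_cohort(default_generator_config(n = n, seed = seed,
                                           overrides = overrides))
}

# a cohort whose outcome is exactly linear in the encoded features (no noise,
# no saturating transforms, no categorical level offsets): the generator's
# structural function is then a smooth recoverable ground truth
linear_cohort_overrides <- function(noise_sd = 0) {
  list(
    noise_sd = noise_sd,
    features = list(
      afc = list(transform = "linear"),
      e2_hcg = list(transform = "linear"),
      infertility_type = list(offsets = c(0, 0)),
      infertility_cause = list(offsets = rep(0, 6)),
      therapeutic_regimen = list(offsets = rep(0, 5))
    )
  )
}

expect_cohort_valid <- function(cohort) {
  testthat::expect_silent(validate_cohort(cohort))
}
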