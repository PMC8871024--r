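# ovaresp

Regression modelling of the ovarian response to controlled ovarian
stimulation (COS), with perturbation-based ranking of the clinical impact
features.

In an IVF cycle, gonadotropin (Gn) stimulation aims to retrieve multiple
oocytes; the retrieved count largely determines the cycle's prospects, and
both extremes are risky (fewer than 6 oocytes: likely cancellation; more
than 18: risk of ovarian hyperstimulation syndrome). `ovaresp` is for
reproductive-medicine researchers and methodologists who want a tested,
reproducible pipeline that

1. **generates synthetic clinical cohorts** calibrated to the reported
   marginal structure of a reference 1365-woman IVF cohort (13 candidate impact
   features — age, infertility type/duration/cause, BMI, AFC, bFSH, basal
   E2, AMH, therapeutic regimen, days and dosage of Gn, E2 on the trigger
   day — plus the oocyte count, 0–29), with a clinically motivated
   dependence structure including dose-by-indication confounding;
2. **screens features** by univariate Pearson correlation with the outcome
   (two-sided p from the t transform, selection at p < 0.05);
3. **trains two regressors** of the oocyte count behind one predictor
   contract: a feed-forward network 11→4→6→1 (sigmoid hidden layers, linear
   output) trained by Levenberg–Marquardt with L2 regularization and
   early stopping, and an ε-insensitive Gaussian-kernel support vector
   regressor (ε = 0.5 oocytes, hyperparameters by 10-fold CV);
4. **evaluates and selects** (RMSE, regression coefficient R of predicted
   vs actual, error fractions ≤3 / ≤5 oocytes);
5. **ranks features** by the normalized mean impact value

   MIV_i = (1/m) Σ_j [ F(…, 1.1·h_i⁽ʲ⁾, …) − F(…, 0.9·h_i⁽ʲ⁾, …) ],
   NMIV = MIV / max|MIV|,

   the cohort-average prediction change under a ±10% perturbation of one
   raw feature, normalized so the top feature scores exactly 1; and
6. **tailors the Gn dose** toward a target oocyte number by bracketed
   bisection on the model's prediction, with poor/normal/high response
   flags.

## Worked example

```r
library(ovaresp)

cohort <- generate_cohort(default_generator_config(seed = 7))
screen <- pearson_screen(cohort, alpha = 0.05)
screen
#> Pearson feature screen (alpha = 0.05 , n = 1365 ): 11 of 13 features selected
#>               feature      r   p_value selected note
#>                   age -0.275  3.85e-25     TRUE
#>      infertility_type -0.107  7.43e-05     TRUE
#>  infertility_duration -0.165  9.36e-10     TRUE
#>                   bmi  0.007  8.09e-01    FALSE
#>                   afc  0.677 2.24e-183     TRUE
#>                  bfsh -0.198  1.74e-13     TRUE
#>              basal_e2 -0.016  5.62e-01    FALSE
#>                   amh  0.531 2.71e-100     TRUE
#>     infertility_cause -0.156  6.63e-09     TRUE
#>   therapeutic_regimen -0.126  3.17e-06     TRUE
#>               days_gn  0.182  1.31e-11     TRUE
#>             dosage_gn -0.181  1.68e-11     TRUE
#>                e2_hcg  0.695 3.95e-197     TRUE
```

BMI and basal E2 (the two null features in the generator) are the two
features dropped. The network is trained on the 11 selected features and
evaluated on all records:

```r
fit <- train_ann(cohort, selected_features(screen), seed = 7,
                 split = split_spec(seed = 7))
evaluate_model(fit, cohort)
#> Model evaluation (full_cohort, n = 1365)
#>   RMSE: 3.099 oocytes
#>   regression coefficient R: 0.896
#>   |error| <= 3: 65.93%
#>   |error| <= 5: 89.23%
```

So the fitted count tracks the observed count with correlation 0.896, and
89% of women are predicted within 5 oocytes. Importance ranking:

```r
feature_importance(fit, cohort, screen)
#> Perturbation-based feature importance (NMIV), 11 features
#>               feature     miv   nmiv rank      r               sign_note
#>                   afc  0.7993  1.000    1  0.677
#>                e2_hcg  0.6971  0.872    2  0.695
#>   therapeutic_regimen -0.5125 -0.641    3 -0.126 encoding-dependent sign
#>      infertility_type -0.4066 -0.509    4 -0.107 encoding-dependent sign
#>     infertility_cause -0.3398 -0.425    5 -0.156 encoding-dependent sign
#>                   age -0.3291 -0.412    6 -0.275
#>                   amh  0.2641  0.330    7  0.531
#>             dosage_gn  0.2270  0.284    8 -0.181
#>               days_gn  0.2174  0.272    9  0.182
#>                  bfsh -0.1377 -0.172   10 -0.198
#>  infertility_duration -0.1143 -0.143   11 -0.165
```

The antral follicle count dominates (NMIV = 1), followed by the estradiol
level on the trigger day. Note the Gn dosage: its *univariate* correlation
with the yield is negative (r = −0.181, a dose-by-indication artifact —
poor-reserve patients receive more Gn) while its model-based impact is
positive (NMIV = +0.284), which is exactly the confound the perturbation
statistic is designed to see through. Categorical rows carry a sign note
because their sign depends on the arbitrary integer encoding.

Clinical decision support for one woman:

```r
patient <- cohort[42, ]
predict(fit, patient)            # 6.41 oocytes expected at her current plan
flag_response_risk(predict(fit, patient))
#> [1] "normal"
tailor_gn_dose(fit, patient, target_count = 9, dose_bounds = c(300, 6000))
#> Gn dose tailoring: target achieved
#>   recommended dose: 4480.0 IU -> predicted 8.58 oocytes (17 evaluations)
```

An unreachable target returns the boundary dose flagged as not achievable
rather than erroring. `run_pipeline(run_config(seed = 1), "out/")` executes
the whole chain and writes every artifact (cohort and screening CSVs, both
serialized models, evaluation reports, the importance table) plus a
manifest with seeds and file hashes; reruns are byte-identical.

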