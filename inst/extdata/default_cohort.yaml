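# Default synthetic-cohort calibration.
#
# Continuous marginals are truncated normal (age, bmi) or truncated log-normal
# (right-skewed positive features); `mean` is the target cohort mean, bounds are
# the observed clinical ranges, and the location parameter is solved at load
# time so the truncated mean matches the target. `weight` is the signed effect
# (oocytes per SD of the transformed feature) in the structural outcome model;
# BMI and basal E2 are inert by design. Saturating (logistic) transforms on AFC
# and E2-on-HCG-day encode the diminishing marginal yield of very high ovarian
# reserve/response. Categorical features carry additive level offsets (oocytes),
# centered at load time. The Gaussian copula induces the clinical dependence
# structure: an ovarian-reserve cluster (AFC, AMH, bFSH, E2 on HCG day), age
# effects, and dose-by-indication confounding of the Gn dosage (poor reserve
# receives more Gn), which gives the dosage a negative marginal correlation
# with the outcome despite its positive structural effect.
version: 1
"n": 1365
seed: 20220214
noise_sd: 2.9
intercept: 11.19
features:
  age:
    dist: truncnorm
    mean: 32.44
    scale: 4.69
    transform: linear
    weight: -0.22
  infertility_type:
    counts: [680, 685]
    offsets: [0.95, -0.95]
  infertility_duration:
    dist: trunclnorm
    mean: 3.6
    scale: 0.75
    transform: linear
    weight: -0.65
  bmi:
    dist: truncnorm
    mean: 22.27
    scale: 3.43
    transform: linear
    weight: 0.0
  afc:
    dist: trunclnorm
    mean: 19.6
    scale: 0.563
    transform: logistic
    center: 25
    width: 14
    weight: 2.6
  bfsh:
    dist: trunclnorm
    mean: 9.37
    scale: 0.817
    transform: linear
    weight: -0.55
  basal_e2:
    dist: trunclnorm
    mean: 83.96
    scale: 1.16
    transform: linear
    weight: 0.0
  amh:
    dist: trunclnorm
    mean: 3.15
    scale: 0.88
    transform: linear
    weight: 1.3
  infertility_cause:
    counts: [444, 112, 173, 72, 494, 70]
    offsets: [1.12, 2.94, -2.24, -0.70, -0.91, -1.26]
  therapeutic_regimen:
    counts: [222, 385, 332, 309, 117]
    offsets: [1.35, 1.5, -0.38, -1.28, -1.65]
  days_gn:
    dist: trunclnorm
    mean: 10.51
    scale: 0.30
    transform: linear
    weight: 0.33
  dosage_gn:
    dist: trunclnorm
    mean: 2270.15
    scale: 0.35
    transform: linear
    weight: 0.4
  e2_hcg:
    dist: trunclnorm
    mean: 2284.6
    scale: 0.942
    transform: logistic
    center: 3500
    width: 3000
    weight: 3.8
copula:
  - [age, afc, -0.45]
  - [age, amh, -0.40]
  - [age, infertility_duration, 0.45]
  - [age, dosage_gn, 0.30]
  - [age, bfsh, 0.20]
  - [afc, amh, 0.65]
  - [afc, e2_hcg, 0.40]
  - [afc, dosage_gn, -0.50]
  - [afc, bfsh, -0.25]
  - [afc, days_gn, 0.22]
  - [afc, infertility_duration, -0.15]
  - [amh, e2_hcg, 0.30]
  - [amh, dosage_gn, -0.40]
  - [amh, bfsh, -0.25]
  - [days_gn, dosage_gn, 0.55]
  - [days_gn, e2_hcg, 0.10]
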