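n_individuals: 2393.0
snps:
- rsid: rs12785878
  gene: DHCR7/NADSYN1
  functional_class: synthesis
  coded_allele: vitd_increasing
  grs_weight: 1.0
- rsid: rs10741657
  gene: CYP2R1
  functional_class: synthesis
  coded_allele: vitd_increasing
  grs_weight: 1.0
- rsid: rs2282679
  gene: GC
  functional_class: transport
  coded_allele: vitd_increasing
  grs_weight: 1.0
- rsid: rs6013897
  gene: CYP24A1
  functional_class: catabolism
  coded_allele: vitd_increasing
  grs_weight: 1.0
allele_freqs:
- 0.45000000000000001
- 0.40000000000000002
- 0.29999999999999999
- 0.25
vitd_intercept: 37.100000000000001
per_allele_effects:
- 2.1400000000000001
- 1.1000000000000001
- 2.9399999999999999
- 0.73999999999999999
vitd_noise_sd: 16.0
confounder_effect_on_vitd: -5.0
causal_log_or_per_nmol: -0.0040000000000000001
confounder_log_or: 0.29999999999999999
pleiotropy_log_or:
- 0
- 0
- 0
- 0
outcome_baseline_log_odds: -1.6000000000000001
covariate_spec:
  age_mean: 59.0
  age_sd: 7.0
  age_min: 45.0
  p_female: 0.59999999999999998
  income_levels:
  - <2000
  - 2000-3499
  - 3500-4999
  - '>=5000'
  income_probs:
  - 0.34999999999999998
  - 0.29999999999999999
  - 0.20000000000000001
  - 0.14999999999999999
  smoking_levels:
  - never
  - former
  - current
  smoking_probs:
  - 0.59999999999999998
  - 0.12
  - 0.28000000000000003
  alcohol_levels:
  - never
  - former
  - current
  alcohol_probs:
  - 0.62
  - 0.080000000000000002
  - 0.29999999999999999
  p_physical_activity: 0.34999999999999998
  p_family_history: 0.14999999999999999
biomarker_spec:
  vitd_ref: 42.0
  fbg:
    dist: lognormal
    log_mean: 1.6863989535702288
    vitd_slope: -0.0015
    conf_slope: 0.01
    log_sd: 0.14999999999999999
  insulin:
    dist: lognormal
    log_mean: 2.4423470353692043
    vitd_slope: -0.0054999999999999997
    conf_slope: 0.059999999999999998
    log_sd: 0.40000000000000002
  tg:
    dist: lognormal
    log_mean: -0.051293294387550578
    vitd_slope: -0.0070000000000000001
    conf_slope: 0.080000000000000002
    log_sd: 0.45000000000000001
  hdl:
    dist: lognormal
    log_mean: 0.23901690047049992
    vitd_slope: 0.0030000000000000001
    conf_slope: -0.050000000000000003
    log_sd: 0.25
  ogtt:
    dist: lognormal
    log_mean: 1.8718021769015913
    vitd_slope: -0.0030000000000000001
    conf_slope: 0.059999999999999998
    log_sd: 0.29999999999999999
    p_missing: 0.59999999999999998
  sbp:
    dist: normal
    mean: 124.0
    vitd_slope: -0.050000000000000003
    conf_slope: 4.0
    sd: 15.0
  dbp:
    dist: normal
    mean: 77.0
    vitd_slope: -0.040000000000000001
    conf_slope: 2.5
    sd: 9.0
  wc:
    dist: normal
    mean: 78.0
    vitd_slope: -0.25
    conf_slope: 3.0
    sd: 8.0
  weight:
    dist: normal
    mean: 61.0
    vitd_slope: -0.10000000000000001
    conf_slope: 2.0
    sd: 10.0
  height:
    dist: normal
    mean: 1.6200000000000001
    vitd_slope: 0.0
    conf_slope: 0.0
    sd: 0.080000000000000002
  hip_offset:
    mean: 10.0
    sd: 4.0
  med_probs:
    tg_lowering: 0.050000000000000003
    hdl_raising: 0.01
    antihypertensive: 0.22
    antidiabetic: 0.050000000000000003
    prior_t2d_diagnosis: 0.040000000000000001
seed: 1
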