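# Gail-model configuration: category relative risks and baseline hazards.
# Category RRs follow the published case-control decomposition (menarche
# age; biopsies with an age-50 split and an atypical-hyperplasia
# multiplier; age-at-first-live-birth by first-degree-relative count
# interaction). Baseline composite breast-cancer incidence (h1) and
# competing non-breast mortality (h2) are annual rates per 100,000 in
# 5-year bands, an implementer-sourced approximation of the white-female
# SEER-based rates used by the published absolute-risk projection, with
# the attributable-risk deflator (1 - AR) split at age 50. Strata outside
# the published set map to the default stratum with a warning.
calculator: gail
version: "1.0"
horizon_years: 5
eligibility: {sex: female, min_age: 35, max_age: 85}
required: [menarche_age, first_birth, breast_biopsy_count]
relative_risks:
  menarche_age:                       # age at menarche, years
    - {min: 14, rr: 1.000}
    - {min: 12, rr: 1.099}
    - {min: 0,  rr: 1.207}
  biopsy_under50: [1.00, 1.70, 2.88]  # 0 / 1 / 2+ biopsies, current age < 50
  biopsy_50plus:  [1.00, 1.27, 1.62]  # 0 / 1 / 2+ biopsies, current age >= 50
  atypical_hyperplasia:               # multiplier, applies only with >= 1 biopsy
    ah: 1.82
    no_ah: 0.93
    unknown: 1.00
  first_birth_fdr:
    # rows: age at first live birth < 20, 20-24, 25-29 (or nulliparous), >= 30
    # cols: number of affected first-degree relatives 0 / 1 / 2+
    bands: [20, 25, 30]
    table:
      - [1.000, 2.607, 6.798]
      - [1.244, 2.681, 5.775]
      - [1.548, 2.756, 4.907]
      - [1.927, 2.834, 4.169]
baseline:
  default_stratum: white
  strata:
    white:
      ages: [20,   25,   30,   35,    40,    45,    50,    55,    60,    65,    70,    75,    80]
      h1:   [1.0,  7.6,  26.6, 66.1,  126.5, 186.6, 221.1, 272.1, 334.8, 392.3, 417.8, 443.9, 443.9]
      h2:   [44,   53,   74,   108,   163,   248,   395,   624,   1001,  1614,  2572,  4258,  7228]
  one_minus_ar: {under50: 0.5788, from50: 0.9399}
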