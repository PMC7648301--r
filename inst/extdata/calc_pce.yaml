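# Pooled cohort equations for 10-year atherosclerotic cardiovascular
# disease risk (ACC/AHA), race- and sex-stratified with age interactions:
#   risk = 1 - S0 ^ exp(sum(terms) - sum(terms at reference))
# Term structure is fixed in code (ln age, ln age squared, ln lipids and
# their age interactions, treated/untreated ln SBP, smoking and its age
# interaction, diabetes); coefficients are implementer-sourced from the
# published equations. A coefficient of 0 switches a term off for a
# stratum. Race strata outside {white, black} map to white with a warning.
calculator: pce
version: "1.0"
horizon_years: 10
eligibility: {min_age: 40, max_age: 79}
required: [age, sex, race_ethnicity, total_cholesterol, HDL, systolic_bp, treated_hypertension, smoker, diabetes]
default_race: white
strata:
  white_female:
    baseline_survival: 0.9665
    coefficients:
      ln_age: -29.799
      ln_age_sq: 4.884
      ln_tc: 13.540
      ln_age_ln_tc: -3.114
      ln_hdl: -13.578
      ln_age_ln_hdl: 3.149
      ln_sbp_treated: 2.019
      ln_age_ln_sbp_treated: 0
      ln_sbp_untreated: 1.957
      ln_age_ln_sbp_untreated: 0
      smoker: 7.574
      ln_age_smoker: -1.665
      diabetes: 0.661
    reference: {age: 55, total_cholesterol: 213, HDL: 50, systolic_bp: 120}
  black_female:
    baseline_survival: 0.9533
    coefficients:
      ln_age: 17.114
      ln_age_sq: 0
      ln_tc: 0.940
      ln_age_ln_tc: 0
      ln_hdl: -18.920
      ln_age_ln_hdl: 4.475
      ln_sbp_treated: 29.291
      ln_age_ln_sbp_treated: -6.432
      ln_sbp_untreated: 27.820
      ln_age_ln_sbp_untreated: -6.087
      smoker: 0.691
      ln_age_smoker: 0
      diabetes: 0.874
    reference: {age: 55, total_cholesterol: 213, HDL: 50, systolic_bp: 120}
  white_male:
    baseline_survival: 0.9144
    coefficients:
      ln_age: 12.344
      ln_age_sq: 0
      ln_tc: 11.853
      ln_age_ln_tc: -2.664
      ln_hdl: -7.990
      ln_age_ln_hdl: 1.769
      ln_sbp_treated: 1.797
      ln_age_ln_sbp_treated: 0
      ln_sbp_untreated: 1.764
      ln_age_ln_sbp_untreated: 0
      smoker: 7.837
      ln_age_smoker: -1.795
      diabetes: 0.658
    reference: {age: 55, total_cholesterol: 213, HDL: 48, systolic_bp: 120}
  black_male:
    baseline_survival: 0.8954
    coefficients:
      ln_age: 2.469
      ln_age_sq: 0
      ln_tc: 0.302
      ln_age_ln_tc: 0
      ln_hdl: -0.307
      ln_age_ln_hdl: 0
      ln_sbp_treated: 1.916
      ln_age_ln_sbp_treated: 0
      ln_sbp_untreated: 1.809
      ln_age_ln_sbp_untreated: 0
      smoker: 0.549
      ln_age_smoker: 0
      diabetes: 0.645
    reference: {age: 55, total_cholesterol: 213, HDL: 48, systolic_bp: 120}
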