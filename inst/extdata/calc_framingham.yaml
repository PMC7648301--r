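# Framingham general cardiovascular disease risk (2008 lipid-based form),
# sex-stratified proportional-hazards equation:
#   risk = 1 - S0 ^ exp(sum(beta * x) - sum(beta * x_ref))
# Continuous inputs enter log-transformed; systolic blood pressure carries
# separate coefficients for treated and untreated hypertension.
# Coefficients are implementer-sourced from the published equation; the
# reference profile (a non-smoking, non-diabetic, untreated individual at
# the cohort's mean continuous values) anchors the exponent, so the
# calculator returns 1 - S0 exactly at the reference inputs.
calculator: framingham
version: "1.0"
horizon_years: 10
eligibility: {min_age: 30, max_age: 74}
required: [age, sex, total_cholesterol, HDL, systolic_bp, treated_hypertension, smoker, diabetes]
strata:
  female:
    baseline_survival: 0.95012
    coefficients:
      ln_age: 2.32888
      ln_tc: 1.20904
      ln_hdl: -0.70833
      ln_sbp_untreated: 2.76157
      ln_sbp_treated: 2.82263
      smoker: 0.52873
      diabetes: 0.69154
    reference: {age: 49, total_cholesterol: 215, HDL: 57, systolic_bp: 125}
  male:
    baseline_survival: 0.88936
    coefficients:
      ln_age: 3.06117
      ln_tc: 1.12370
      ln_hdl: -0.93263
      ln_sbp_untreated: 1.93303
      ln_sbp_treated: 1.99881
      smoker: 0.65451
      diabetes: 0.57367
    reference: {age: 49, total_cholesterol: 213, HDL: 45, systolic_bp: 129}
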