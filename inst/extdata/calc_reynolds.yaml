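# Reynolds risk score: 10-year cardiovascular risk with high-sensitivity
# C-reactive protein and parental premature MI, sex-specific published
# forms (age enters linearly for women, log-transformed for men).
#   risk = 1 - S0 ^ exp(B - B_ref)
# hsCRP is the input that is rarely available in routine care, which is
# why this calculator is the one most often left uncomputed.
calculator: reynolds
version: "1.0"
horizon_years: 10
eligibility: {min_age: 45, max_age: 80}
required: [age, sex, systolic_bp, total_cholesterol, HDL, hsCRP, smoker, parental_MI_before_60]
strata:
  female:
    baseline_survival: 0.98634
    coefficients:
      age: 0.0799
      ln_sbp: 3.137
      ln_hscrp: 0.180
      ln_tc: 1.382
      ln_hdl: -1.172
      smoker: 0.818
      parental_mi: 0.438
    reference: {age: 52, systolic_bp: 125, hsCRP: 2.0, total_cholesterol: 210, HDL: 52}
  male:
    baseline_survival: 0.89900
    coefficients:
      ln_age: 4.385
      ln_sbp: 2.607
      ln_hscrp: 0.180
      ln_tc: 0.963
      ln_hdl: -0.772
      smoker: 0.405
      parental_mi: 0.541
    reference: {age: 58, systolic_bp: 126, hsCRP: 1.8, total_cholesterol: 205, HDL: 46}
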