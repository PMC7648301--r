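# Tyrer-Cuzick model in its published single-hypothetical-locus
# simplification: lifetime (to age 85) breast-cancer risk combining the
# Mendelian carrier posterior over BRCA1/BRCA2 plus one common dominant
# low-penetrance locus, with hormonal and benign-disease relative risks
# applied to the non-high-risk-gene component of the mixture
# (noncarriers and hypothetical-locus carriers); the high-risk-gene
# component is dominated by genotype and left unscaled. This is an
# approximation of the commercial IBIS program; hormonal RRs are
# implementer-sourced, modest, and multiplicative.
calculator: tyrer_cuzick
version: "1.0"
lifetime_to_age: 85
eligibility: {sex: female, min_age: 20, max_age: 85}
required: [age, menarche_age, first_birth, hrt_use]
gene_model: gene_model_tc.yaml
hormonal_relative_risks:
  menarche_age:
    - {min: 14, rr: 1.00}
    - {min: 12, rr: 1.10}
    - {min: 0,  rr: 1.22}
  first_birth:                 # age at first live birth
    nulliparous: 1.25
    bands: [{min: 30, rr: 1.30}, {min: 25, rr: 1.18}, {min: 20, rr: 1.08}, {min: 0, rr: 1.00}]
  hrt_use: {never: 1.00, former: 1.02, current: 1.40}
  atypical_hyperplasia: {ah: 4.00, no_ah: 1.00, unknown: 1.00}
  bmi: [{min: 30, rr: 1.25}, {min: 25, rr: 1.10}, {min: 0, rr: 1.00}]
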