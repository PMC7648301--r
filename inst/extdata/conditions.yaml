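# Versioned catalog of the 27 risk-assessed conditions.
# The intake vocabulary of the source platform is unpublished; this list is a
# configurable stand-in covering every condition referenced by the default
# rule catalog and the clustering examples. Codes are stable identifiers;
# labels are display only. sex: restricts who can carry the condition.
version: "1.0"
conditions:
  - {code: breast_cancer,                 label: "Breast cancer",                        sex: any}
  - {code: ovarian_cancer,                label: "Ovarian cancer",                       sex: female}
  - {code: colon_cancer,                  label: "Colorectal cancer",                    sex: any}
  - {code: endometrial_cancer,            label: "Endometrial (uterine) cancer",         sex: female}
  - {code: prostate_cancer,               label: "Prostate cancer",                      sex: male}
  - {code: lung_cancer,                   label: "Lung cancer",                          sex: any}
  - {code: pancreatic_cancer,             label: "Pancreatic cancer",                    sex: any}
  - {code: gastric_cancer,                label: "Gastric cancer",                       sex: any}
  - {code: melanoma,                      label: "Melanoma",                             sex: any}
  - {code: thyroid_cancer,                label: "Thyroid cancer",                       sex: any}
  - {code: colorectal_polyposis,          label: "Colorectal polyposis (>10 adenomas)",  sex: any}
  - {code: marfan_syndrome,               label: "Marfan syndrome",                      sex: any}
  - {code: thalassemia,                   label: "Thalassemia",                          sex: any}
  - {code: hypertrophic_cardiomyopathy,   label: "Hypertrophic cardiomyopathy",          sex: any}
  - {code: long_qt_syndrome,              label: "Long QT syndrome",                     sex: any}
  - {code: sudden_cardiac_death,          label: "Sudden cardiac death",                 sex: any}
  - {code: familial_hypercholesterolemia, label: "Familial hypercholesterolemia",        sex: any}
  - {code: hemochromatosis,               label: "Hereditary hemochromatosis",           sex: any}
  - {code: wilson_disease,                label: "Wilson disease",                       sex: any}
  - {code: alpha1_antitrypsin_deficiency, label: "Alpha-1 antitrypsin deficiency",       sex: any}
  - {code: venous_thromboembolism,        label: "Venous thromboembolism (DVT/PE)",      sex: any}
  - {code: abdominal_aortic_aneurysm,     label: "Abdominal aortic aneurysm",            sex: any}
  - {code: coronary_artery_disease,       label: "Coronary artery disease / MI",         sex: any}
  - {code: stroke,                        label: "Stroke",                               sex: any}
  - {code: type_1_diabetes,               label: "Type 1 diabetes mellitus",             sex: any}
  - {code: type_2_diabetes,               label: "Type 2 diabetes mellitus",             sex: any}
  - {code: asthma,                        label: "Asthma",                               sex: any}
# Extension point: conditions outside the risk catalog are entered with
# code "other" plus a free-text label; they are stored and reported but
# never drive a rule or calculator.
other_code: other
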