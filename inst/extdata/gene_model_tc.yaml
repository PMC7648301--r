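# Gene model used by the Tyrer-Cuzick simplification: the two high-risk
# breast/ovarian genes plus one hypothetical dominant low-penetrance
# susceptibility locus that absorbs residual familial aggregation. The
# hypothetical locus is common and confers a moderate lifetime breast-cancer
# risk; it does not affect ovarian risk. Numeric values are implementer-
# sourced approximations of the published single-hypothetical-locus model.
model: tyrer_cuzick_three_gene
version: "1.0"
genes:
  BRCA1:
    allele_frequency: {general: 0.00060, ashkenazi: 0.00600}
  BRCA2:
    allele_frequency: {general: 0.00069, ashkenazi: 0.00680}
  LOWPEN:
    allele_frequency: {general: 0.11000, ashkenazi: 0.11000}
cancers:
  breast:
    condition: breast_cancer
    female:
      ages:       [20,     30,    40,    50,    60,    70,    80,    90,    110]
      noncarrier: [0.0001, 0.003, 0.010, 0.028, 0.050, 0.072, 0.088, 0.095, 0.098]
      BRCA1:      [0.001,  0.050, 0.210, 0.390, 0.540, 0.620, 0.670, 0.690, 0.700]
      BRCA2:      [0.001,  0.030, 0.130, 0.270, 0.420, 0.530, 0.600, 0.630, 0.640]
      LOWPEN:     [0.001,  0.010, 0.050, 0.110, 0.170, 0.220, 0.250, 0.255, 0.260]
    male:
      ages:       [20,      40,      60,     80,     110]
      noncarrier: [0.0,     0.00005, 0.0003, 0.0008, 0.0010]
      BRCA1:      [0.0,     0.001,   0.005,  0.012,  0.0150]
      BRCA2:      [0.0,     0.010,   0.040,  0.070,  0.0800]
      LOWPEN:     [0.0,     0.00005, 0.0003, 0.0008, 0.0010]
  ovarian:
    condition: ovarian_cancer
    female:
      ages:       [20,  30,     40,    50,    60,    70,    80,    110]
      noncarrier: [0.0, 0.0005, 0.002, 0.005, 0.009, 0.012, 0.014, 0.015]
      BRCA1:      [0.0, 0.010,  0.060, 0.190, 0.330, 0.400, 0.440, 0.450]
      BRCA2:      [0.0, 0.002,  0.010, 0.040, 0.100, 0.140, 0.170, 0.180]
      LOWPEN:     [0.0, 0.0005, 0.002, 0.005, 0.009, 0.012, 0.014, 0.015]
    male:
      ages:       [20,  110]
      noncarrier: [0.0, 0.0]
      BRCA1:      [0.0, 0.0]
      BRCA2:      [0.0, 0.0]
      LOWPEN:     [0.0, 0.0]
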