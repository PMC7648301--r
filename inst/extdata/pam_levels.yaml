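# Patient Activation Measure level boundaries (4-level scheme, the one
# used for all reported activation results). Raw scores run 0-100; upper
# bounds are inclusive: level 1 <= 47.0 < level 2 <= 55.1 < level 3
# <= 67.0 < level 4.
version: "1.0"
cut_points: [47.0, 55.1, 67.0]
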