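id: "3_15"
diameter_mm: 3
modality: CT
min_feature_distance_mm: 15
centroids_mm:
  - [-17.51, -29.29, -5.00]
  - [-0.88, 14.82, -5.00]
  - [23.65, -18.23, -5.00]
  - [-17.77, 27.33, -5.00]
  - [26.97, -31.01, 5.00]
  - [18.86, 4.98, 5.00]
  - [-2.72, 25.95, 5.00]
  - [-30.61, 5.44, 5.00]
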