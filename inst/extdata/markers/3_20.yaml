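id: "3_20"
diameter_mm: 3
modality: CT
min_feature_distance_mm: 20
centroids_mm:
  - [-30.84, -16.53, -5.00]
  - [27.73, 32.80, -5.00]
  - [-30.84, -36.53, -5.00]
  - [19.73, -13.51, -5.00]
  - [4.98, 32.44, 5.00]
  - [38.31, 9.87, 5.00]
  - [-30.84, 25.96, 5.00]
  - [1.87, -34.49, 5.00]
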