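# Reduced desk-scale configuration (the package default).
scale: scaled
grid:
  tissue_dims: [40, 16, 4.8]   # mm
  blood_above: 13              # mm
  blood_below: 3.2             # mm
  h: 0.3                       # voxel edge, mm
catheter:
  distal_length: 8
  distal_diameter: 2.7
  me_diameter: 1
  me_offset_from_tip: 2
  isolation_thickness: 0.2
  shaft_length: 4
t_end: 55                      # ms
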