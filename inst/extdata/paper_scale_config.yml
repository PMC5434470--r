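# Full-size setup: 80 x 24 x 4.8 mm slab, 24.6 / 6.6 mm blood layers.
# Expect hours per scenario on a single core.
scale: paper
grid:
  tissue_dims: [80, 24, 4.8]
  blood_above: 24.6
  blood_below: 6.6
  h: 0.3
catheter:
  distal_length: 8
  distal_diameter: 2.7
  me_diameter: 1
  me_offset_from_tip: 2
  isolation_thickness: 0.2
  shaft_length: 10
t_end: 115
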