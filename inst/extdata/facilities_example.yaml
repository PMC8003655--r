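# Example facility acquisition specs (synthetic).  Each entry maps a
# facility id to facility_spec() fields; omitted fields use the identity
# defaults.  slice_thickness_factor emulates thick axial slices (clinical
# multi-facility data ranges from about 3.3 to 9 mm against ~1 mm in-plane).
A: {}
B:
  gamma: 1.8
  noise_sigma: 0.08
  bias_field_amplitude: 0.2
  slice_thickness_factor: 2
  rng_seed_offset: 101
C:
  intensity_scale: [1.1, 0.9, 1.0, 1.05]
  intensity_offset: [0.02, 0.0, -0.02, 0.0]
  gamma: 0.8
  noise_sigma: 0.04
  bias_field_amplitude: 0.1
  slice_thickness_factor: 4
  rng_seed_offset: 202
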