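# Full-length motor, single mNeonGreen tag per monomer. Mostly static
# binders; processive events are rare and velocities are bimodal
# (slow-moving majority with intermittent pauses, fast minority).
# Component s.d. = published s.e.m._i * sqrt(weight_i * n), n = 61.
motor:
  name: CENP-E_FL-mNeon
  landing_rate_total: 0.147      # events / (um * min)
  processive_fraction: 0.061
  velocity_components:
    - {weight: 0.75, mean: 46.4,   sd: 12.716}   # nm/s, slow population
    - {weight: 0.25, mean: 157.98, sd: 42.058}   # nm/s, fast population
  run_length_mean: 1258.9        # nm
  residency_mean: 37.1           # s
  pause_entry_rate: 0.0
  pause_exit_rate: 0.0
  static_dwell_mean: 1.0
  detach_mode: per_distance
  n_fluorophores: 2              # one mNeon per monomer, dimer
  bleach_rate: 0.05
optics:
  pixel_size: 160
  frame_interval: 0.12
  exposure: 0.1
  psf_sigma: 130
  photons_per_fluorophore_per_frame: 200
  background_mean: 100
  read_noise_sd: 3
  duration: 120
  image_shape: [128, 128]
field:
  n_mts: 98
  length_mean_um: 10
  length_sd_um: 2
seed: 42
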