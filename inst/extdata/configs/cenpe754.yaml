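# Stalk-stabilised dimeric motor truncation, tandem 2x mNeonGreen tag.
# Velocity s.d. is the published s.e.m. scaled by sqrt(n) (2.4 * sqrt(289)).
motor:
  name: CENP-E_754-2mNeon
  landing_rate_total: 0.392      # events / (um * min)
  processive_fraction: 0.513
  velocity_components:
    - {weight: 1.0, mean: 180.0, sd: 40.8}   # nm/s
  run_length_mean: 703.3         # nm
  residency_mean: 5.3            # s
  pause_entry_rate: 0.0          # /s
  pause_exit_rate: 0.0           # /s
  static_dwell_mean: 1.0         # s
  detach_mode: per_distance
  n_fluorophores: 4              # 2x mNeon per monomer, dimer
  bleach_rate: 0.05              # /s per fluorophore
optics:
  pixel_size: 160                # nm
  frame_interval: 0.12           # s
  exposure: 0.1                  # s
  psf_sigma: 130                 # nm
  photons_per_fluorophore_per_frame: 200
  background_mean: 100
  read_noise_sd: 3
  duration: 60                   # s
  image_shape: [128, 128]
field:
  n_mts: 100
  length_mean_um: 10
  length_sd_um: 2
seed: 42
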