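# Kinesin-1 truncation (K560) control with tandem 2x mNeonGreen, used as the
# fluorophore-count / initial-intensity reference. Its motility parameters
# were not quantified here, so the kinetics below are nominal kinesin-1
# values; the photophysics (4 fluorophores, same tag) are what matter.
motor:
  name: K560-2mNeon
  landing_rate_total: 0.4        # nominal
  processive_fraction: 0.9       # nominal
  velocity_components:
    - {weight: 1.0, mean: 550.0, sd: 100.0}   # nominal kinesin-1
  run_length_mean: 1100.0        # nominal
  residency_mean: 2.0            # nominal
  pause_entry_rate: 0.0
  pause_exit_rate: 0.0
  static_dwell_mean: 1.0
  detach_mode: per_distance
  n_fluorophores: 4
  bleach_rate: 0.05
optics:
  pixel_size: 160
  frame_interval: 0.12
  exposure: 0.1
  psf_sigma: 130
  photons_per_fluorophore_per_frame: 200
  background_mean: 100
  read_noise_sd: 3
  duration: 60
  image_shape: [128, 128]
field:
  n_mts: 100
  length_mean_um: 10
  length_sd_um: 2
seed: 42
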