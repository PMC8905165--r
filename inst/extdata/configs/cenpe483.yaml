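# Short motor truncation (weak dimer): broad velocity distribution,
# short runs, frequent short-lived static interactions.
# Velocity s.d. = published s.e.m. * sqrt(n) (7.7 * sqrt(346)).
# Landing rate was not measured for this construct; nominal value.
motor:
  name: CENP-E_483-2mNeon
  landing_rate_total: 0.3        # nominal
  processive_fraction: 0.5       # nominal
  velocity_components:
    - {weight: 1.0, mean: 144.2, sd: 143.228}
  run_length_mean: 407.3
  residency_mean: 5.41
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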