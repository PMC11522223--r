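phantom:
  kind: worm
  length_um: 1000.0
  max_radius_um: 25.0
  taper: 0.15
  cap_frac: 0.12
  bend_amplitude_um: 40.0
  bend_wavelength_um: 900.0
  bend_phase: 0.6
  semi_axes_um: ~
  bump_amplitude: 0.0
  bump_freq: 3.0
  n_landmarks: 8
  landmark_strength: 0.8
  rng_seed: 1
render:
  n_frames: 96
  period_frames: 64.0
  pixel_size_um: 4.0
  dim:
  - 64
  - 288
  frame_interval_s: 0.4
  drift_px_per_frame:
  - 0.0
  - 0.0
  drift_walk_sd: 0.0
  psf_sigma_px: 1.2
  noise_sigma: 0.02
  bg_level: 0.85
  bg_gradient: 0.05
  contrast: 0.55
  attenuation_um: 25.0
  tail_fade: 0.0
  tail_floor:
  - 0.02
  - 0.85
  seed: 1
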