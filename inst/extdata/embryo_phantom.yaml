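phantom:
  kind: embryo
  length_um: 50.0
  max_radius_um: 15.0
  taper: 0.15
  cap_frac: 0.12
  bend_amplitude_um: 0.0
  bend_wavelength_um: ~
  bend_phase: 0.0
  semi_axes_um:
  - 25.0
  - 15.0
  - 15.0
  bump_amplitude: 0.05
  bump_freq: 3.0
  n_landmarks: 3
  landmark_strength: 0.8
  rng_seed: 1
render:
  n_frames: 72
  period_frames: 48.0
  pixel_size_um: 0.5
  dim:
  - 96
  - 160
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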