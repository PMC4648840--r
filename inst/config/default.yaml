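# Default tendondic run configuration.
# All blocks are optional except `seed`; omitted fields take the package
# defaults documented on speckle_params(), specimen_model(), load_protocol(),
# grip_slip_model(), dic_config() and strain_config().
seed: 101
output_dir: tendondic_run

speckle:
  image_width_px: 560        # desk-scale sensor; 1243 x 993 = half the
  image_height_px: 993       # physical rig's 2486 x 1985 sensor
  speckle_density: 0.03      # dots per px^2 (~40% coverage)
  dot_radius_mean_px: 2.0
  dot_radius_sd_px: 0.5
  background_level: 0.15     # methylene-blue-dark tissue
  dot_level: 0.9             # white airbrush dots
  blur_sigma_px: 1.0
  noise_sd: 0.01             # sensor noise, fraction of dynamic range

specimen:
  ref_width_mm: 20
  ref_gauge_length_mm: 35
  cross_section_area_mm2: 55
  modulus_E_MPa: 500
  transverse_coupling: 1.5
  convexity_amplitude_mm: 1.0
  inhomogeneity_amplitude: 0.3
  inhomogeneity_corr_length_mm: 2
  hysteresis_offset_mm: 0.3

protocol:
  preload_N: 48.9
  step1_increment_N: 10
  step1_limit_N: 100
  step2_increment_N: 25
  max_load_N: 628.3
  unload_increment_N: 50
  frames_per_step: 3
  hold_at_max: true

slip:
  bone_block_slip_fraction: 0.33
  tissue_slip_fraction: 0.20

rig:
  scale_mm_per_px: 0.05
  working_distance_mm: 500
  baseline_mm: 140
  plate_width_mm: 24
  plate_height_mm: 6

dic:
  facet_size_px: 21
  step_px: 5
  search_radius_px: 10
  zncc_threshold: 0.8
  tol: 1.0e-4
  max_iter: 50

strain:
  window_facets: 5
  measure: engineering
  min_valid_neighbors: 6
  gaussian_weight: true

analysis:
  central_disc_diameter_mm: 4.0
  grid_mm: 1.0
  damage_threshold_pct: 5.0
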