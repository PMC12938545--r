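# Default pipeline configuration. Values mirror the simulated-cohort study
# conditions; everything is overridable per run.
phantom:
  volume_shape: [80, 80, 80]
  spacing_mm: [1.0, 1.0, 1.0]
  tree_depth: 5
  root_radius_mm: 3.0
  radius_taper: 0.78
  branch_length_mm: 16.0
  length_taper: 0.8
  branch_angle_deg: 32.0
  wall_thickness_mm: 0.8
  vessel_offset_mm: 8.0
  vessel_radius_ratio: 0.75
  hu_lumen: -1000.0
  hu_wall: -200.0
  hu_vessel: 40.0
  hu_parenchyma: -850.0
  noise_sigma_hu: 15.0
  jitter: 0.08
  seed: 1
plugs:
  n_plugs_per_scan: 50        # selected augmentation density
  length_range_mm: [2.0, 20.0]
  occlusion_range: [0.35, 1.0]
  diameter_range_mm: [1.0, 20.0]
  geometry: mural
  corridor: seed
transfer:
  tolerance_mm: 0.5
augment:
  smooth_sigma_range_mm: [0.0, 0.8]
  noise_sigma_range_hu: [0.0, 10.0]
dataset:
  ratio: [1, 1]
  patch_size: 96
  target_mm: 0.8
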