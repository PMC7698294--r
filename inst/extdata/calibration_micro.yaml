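# Committed calibration: MFC-NFC-CMC-like furnish at nano-run resolution.
# Width law log-uniform over the measured 0.0685-9.8 um span; the layer
# target (mean areal coverage) and full-depth top view were calibrated once
# against the validated computational surface porosity (see the methods
# vignette) and are not tuned per run.
domain_px: [512, 512]
resolution_um_per_voxel: 0.1
target_layers: 0.94
boundary: periodic
lumen: collapsed
population:
  width_range_um: [0.0685, 9.8]
  width_law: log-uniform
  aspect_ratio: 20
  wall_thickness_um: 0.5
  lumen_um: 0.0
  flexibility: 1
depth_voxels: 2048
n_seeds: 20
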