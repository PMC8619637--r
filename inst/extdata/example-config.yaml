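# Example pipeline configuration for a rectified parallel binocular
# endoscope. Camera defaults match the reference rig: focal length 1 mm,
# optical-centre distance (baseline) 0.99 mm.
camera:
  focal_length_mm: 1.0
  baseline_mm: 0.99
  principal_point_px: [159.5, 159.5]
  pixel_size_mm: 0.0015
  # vertical_tolerance_mm defaults to two pixels when omitted

matcher:
  lambda: 0.3          # category persistence threshold (fraction of frames)
  link_radius: 5       # px, nearest-neighbour chaining of detections
  threshold: 0.08      # FAST segment-test contrast
  nonmax_radius: 8     # px, non-maximum suppression
  n_train_frames: 20
  epochs: 30
  learning_rate: 0.001
  batch_size: 64
  dropout: 0.5
  seed: 1

triangulation:
  margin_factor: 10    # super-triangle size, x bounding-box diagonal

tracking:
  frames: [21, 60]
  fps: 25
  fill_gaps: true
  categories: auto3    # the three categories nearest the feature centroid

paths:
  left_dir: frames/left
  right_dir: frames/right
  model: model.rds
  out_dir: out
  mesh_format: obj

log_level: info
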