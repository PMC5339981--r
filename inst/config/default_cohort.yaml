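# Cohort pipeline configuration. Any key omitted here falls back to
# default_cohort_config(); the merged configuration is recorded in the run
# manifest.
phantom:
  severity_counts: {none: 3, mild: 7, moderate: 9, severe: 4}
  grid_n: 96
  n_frames: 20
  frame_dt: 40.0        # ms
  pixel_size: 1.95      # mm
  tilt_range: [5.0, 35.0]   # jet tilt vs plane normal, degrees
  aortic_radius: 15.0   # mm
  base_peak: 50.0       # baseline centreline speed, cm/s
  t_sys: 300.0          # systole duration, ms
encoding:
  noise_sigma: 0.04     # complex noise SD (lumen magnitude = 1)
  background_phase: 0.1 # radians, common to all encodings
  scout_vencs: [200.0, 300.0, 400.0]
  venc_step: 100.0
unwrap:
  method: temporal
quantify:
  mag_frac: 0.15
  flow_frac: 0.05
  window: ejection
stats:
  r_comparison: steiger_dependent
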