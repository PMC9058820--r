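# Example run configuration: sensor at 0.30 m rolled at 0.10 m/s over a
# 0.5 x 0.5 m vegetation patch on a 2.1 x 1.5 m soil surface, after a 30 s
# stationary soil calibration at the transect start.
seed: 42
index: endvi
offset: 0.05
cycle_seconds: 2
calibration_seconds: 30
aggregator: mean
occupancy_threshold: 0.25
sensor:
  height_m: 0.30
  fov_half_angle_deg: 20.5
scene:
  width_m: 2.1
  length_m: 1.5
  patches:
    - x: 1.2
      "y": 0.75
      width: 0.5
      height: 0.5
transect:
  start: [0.2, 0.75]
  end: [2.0, 0.75]
  speed_m_per_s: 0.10
  noise_sigma: 0.01
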