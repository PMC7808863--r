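# Simulation configuration: a 24 h two-group recording in the default arena.
arena:
  width_px: 520
  height_px: 400
  dish_center: [260, 200]
  dish_radius_px: 190
  food_center: [260, 200]
  food_radius_px: 30
  frame_interval_s: 3
groups:
  mock:
    bout_rate_per_h: 2
    bout_duration_shape: 2
    bout_duration_mean_s: 120
    step_mean_px: 2
    step_dispersion: 0.5
    heading_persistence: 0.7
    mode: food_centered
  infected:
    bout_rate_per_h: 2
    bout_duration_shape: 2
    bout_duration_mean_s: 240
    step_mean_px: 4
    step_dispersion: 0.5
    heading_persistence: 0.7
    mode: food_centered
    mode_switch_h: 9
render:
  larva_axis_px: [6, 3]
  larva_intensity: 140
  background_intensity: 30
  food_intensity: 90
  noise_sd: 2
  dropout_prob: 0
  clutter_prob: 0
# master seed: per-larva seeds are derived as (seed + 1000003 * i) mod 2^31-1
seed: 1
duration_h: 24
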