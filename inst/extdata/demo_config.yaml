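# Demo configuration for `mangrovemove run` / run_pipeline(): a fully
# synthetic study on a 15 km archipelago with six collared tigers.
seed: 4
outdir: mangrovemove_demo
simulate:
  n_animals: 6
  duration_days: 30
  extent_m: [15000.0, 15000.0]
  cell_size: 50.0
  channel_count: 5
  width_range: [30.0, 1200.0]
homerange:
  h: 1000.0
  levels: [5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95]
  mask_water_gt: 1000.0
movement:
  min_fixes: 12
  tz_offset_hours: 5.5
crossings:
  n_null: 5
  max_attempts: 10000
habitat:
  hr_level: 95
  zero_sub: 0.01
density: {}
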