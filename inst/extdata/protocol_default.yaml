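probe:
  volume_uL: 2.0
  concentration_pct_wv: 0.35
loading:
  volume_uL: 6.0
  concentration_pct_wv: 2.0
n_loading: 2
tear_volume_uL: 7.0
t1_s: 900.0
t2_s: 1500.0
t3_s: 2400.0
ts_s: 2700.0
instrument:
  focal_diamond_depth_um: 280.0
  tear_film_thickness_um: 3.0
  quench_threshold_pct: 0.38
  snr: 44.0
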