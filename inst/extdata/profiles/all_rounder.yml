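name: all_rounder
body_mass_kg: 70.0
cp_w: 293.0
wprime_j: 27100.0
nodes:
- duration_s: 1.0
  power_w: 1115.0
- duration_s: 15.0
  power_w: 876.0
- duration_s: 30.0
  power_w: 719.0
- duration_s: 45.0
  power_w: 623.0
- duration_s: 60.0
  power_w: 561.0
- duration_s: 120.0
  power_w: 454.0
- duration_s: 180.0
  power_w: 419.0
- duration_s: 240.0
  power_w: 402.0
- duration_s: 300.0
  power_w: 391.0
- duration_s: 600.0
  power_w: 341.0
- duration_s: 1200.0
  power_w: 307.0
- duration_s: 1800.0
  power_w: 290.0
- duration_s: 2700.0
  power_w: 274.0
- duration_s: 3600.0
  power_w: 264.0
- duration_s: 5400.0
  power_w: 249.0
- duration_s: 7200.0
  power_w: 239.0
- duration_s: 14400.0
  power_w: 214.0
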