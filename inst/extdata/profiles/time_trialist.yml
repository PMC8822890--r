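name: time_trialist
body_mass_kg: 70.0
cp_w: 304.0
wprime_j: 21500.0
nodes:
- duration_s: 1.0
  power_w: 978.0
- duration_s: 15.0
  power_w: 777.0
- duration_s: 30.0
  power_w: 647.0
- duration_s: 45.0
  power_w: 567.0
- duration_s: 60.0
  power_w: 516.0
- duration_s: 120.0
  power_w: 431.0
- duration_s: 180.0
  power_w: 403.0
- duration_s: 240.0
  power_w: 390.0
- duration_s: 300.0
  power_w: 382.0
- duration_s: 600.0
  power_w: 342.0
- duration_s: 1200.0
  power_w: 315.0
- duration_s: 1800.0
  power_w: 301.0
- duration_s: 2700.0
  power_w: 289.0
- duration_s: 3600.0
  power_w: 281.0
- duration_s: 5400.0
  power_w: 269.0
- duration_s: 7200.0
  power_w: 261.0
- duration_s: 14400.0
  power_w: 241.0
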