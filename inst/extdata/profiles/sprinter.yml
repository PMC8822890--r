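name: sprinter
body_mass_kg: 70.0
cp_w: 259.0
wprime_j: 32300.0
nodes:
- duration_s: 1.0
  power_w: 1251.0
- duration_s: 15.0
  power_w: 968.0
- duration_s: 30.0
  power_w: 782.0
- duration_s: 45.0
  power_w: 665.0
- duration_s: 60.0
  power_w: 589.0
- duration_s: 120.0
  power_w: 457.0
- duration_s: 180.0
  power_w: 411.0
- duration_s: 240.0
  power_w: 389.0
- duration_s: 300.0
  power_w: 375.0
- duration_s: 600.0
  power_w: 317.0
- duration_s: 1200.0
  power_w: 276.0
- duration_s: 1800.0
  power_w: 257.0
- duration_s: 2700.0
  power_w: 239.0
- duration_s: 3600.0
  power_w: 227.0
- duration_s: 5400.0
  power_w: 211.0
- duration_s: 7200.0
  power_w: 199.0
- duration_s: 14400.0
  power_w: 172.0
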