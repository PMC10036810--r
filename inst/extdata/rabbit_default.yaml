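cells:
  SN:
    zone: atrial
    k: 8.0
    a1: -0.038181640625
    a2: 0.15
    mu1: 0.2
    mu2: 0.3
    eps0: 0.005
    ct: 200.0
  PS1:
    zone: atrial
    k: 8.0
    a1: 0.15
    a2: 0.15
    mu1: 0.06
    mu2: 0.3
    eps0: 0.004
    ct: 300.0
  PS2:
    zone: atrial
    k: 8.0
    a1: 0.14
    a2: 0.14
    mu1: 0.06
    mu2: 0.3
    eps0: 0.01
    ct: 300.0
  PS3:
    zone: atrial
    k: 8.0
    a1: 0.1
    a2: 0.1
    mu1: 0.1
    mu2: 0.3
    eps0: 0.05
    ct: 300.0
  AM1:
    zone: atrial
    k: 8.0
    a1: 0.071
    a2: 0.071
    mu1: 0.1
    mu2: 0.3
    eps0: 0.08
    ct: 300.0
  AM2:
    zone: atrial
    k: 8.0
    a1: 0.071
    a2: 0.071
    mu1: 0.1
    mu2: 0.3
    eps0: 0.08
    ct: 300.0
  AM3:
    zone: atrial
    k: 8.0
    a1: 0.071
    a2: 0.071
    mu1: 0.1
    mu2: 0.3
    eps0: 0.08
    ct: 300.0
  FP1:
    zone: atrial
    k: 8.0
    a1: 0.13
    a2: 0.13
    mu1: 0.06
    mu2: 0.3
    eps0: 0.0135
    ct: 300.0
  FP2:
    zone: atrial
    k: 8.0
    a1: 0.13
    a2: 0.13
    mu1: 0.06
    mu2: 0.3
    eps0: 0.0115
    ct: 300.0
  FP3:
    zone: atrial
    k: 8.0
    a1: 0.13
    a2: 0.13
    mu1: 0.06
    mu2: 0.3
    eps0: 0.0095
    ct: 300.0
  FP4:
    zone: atrial
    k: 8.0
    a1: 0.13
    a2: 0.13
    mu1: 0.06
    mu2: 0.3
    eps0: 0.0085
    ct: 300.0
  FP5:
    zone: atrial
    k: 8.0
    a1: 0.13
    a2: 0.13
    mu1: 0.06
    mu2: 0.3
    eps0: 0.0075
    ct: 300.0
  FP6:
    zone: atrial
    k: 8.0
    a1: 0.13
    a2: 0.13
    mu1: 0.06
    mu2: 0.3
    eps0: 0.0075
    ct: 300.0
  FP7:
    zone: atrial
    k: 8.0
    a1: 0.13
    a2: 0.13
    mu1: 0.06
    mu2: 0.3
    eps0: 0.0095
    ct: 300.0
  FP8:
    zone: atrial
    k: 7.46875
    a1: -0.0005
    a2: 0.295
    mu1: 0.1225
    mu2: 0.3
    eps0: 0.032
    ct: 300.0
  PB:
    zone: his
    k: 7.46875
    a1: -0.0005
    a2: 0.295
    mu1: 0.1025
    mu2: 0.3
    eps0: 0.019
    ct: 300.0
  HB1:
    zone: his
    k: 8.0
    a1: 0.14125
    a2: 0.14125
    mu1: 0.06
    mu2: 0.3
    eps0: 0.01005
    ct: 300.0
  HB2:
    zone: his
    k: 8.0
    a1: 0.14125
    a2: 0.14125
    mu1: 0.06
    mu2: 0.3
    eps0: 0.01005
    ct: 300.0
  HB3:
    zone: his
    k: 8.0
    a1: 0.14125
    a2: 0.14125
    mu1: 0.06
    mu2: 0.3
    eps0: 0.01055
    ct: 300.0
  HB4:
    zone: his
    k: 8.0
    a1: 0.14125
    a2: 0.14125
    mu1: 0.06
    mu2: 0.3
    eps0: 0.01105
    ct: 300.0
  HB5:
    zone: his
    k: 8.0
    a1: 0.14125
    a2: 0.14125
    mu1: 0.06
    mu2: 0.3
    eps0: 0.01155
    ct: 300.0
  HB6:
    zone: his
    k: 8.0
    a1: 0.14125
    a2: 0.14125
    mu1: 0.06
    mu2: 0.3
    eps0: 0.01205
    ct: 300.0
  SP1:
    zone: atrial
    k: 8.075
    a1: 0.1
    a2: 0.1
    mu1: 0.022625
    mu2: 0.3
    eps0: 0.075
    ct: 300.0
  SP2:
    zone: atrial
    k: 8.075
    a1: 0.1
    a2: 0.1
    mu1: 0.022625
    mu2: 0.3
    eps0: 0.075
    ct: 300.0
  SP3:
    zone: atrial
    k: 8.075
    a1: 0.1
    a2: 0.1
    mu1: 0.022625
    mu2: 0.3
    eps0: 0.075
    ct: 300.0
  SP4:
    zone: atrial
    k: 8.075
    a1: 0.1
    a2: 0.1
    mu1: 0.022625
    mu2: 0.3
    eps0: 0.075
    ct: 300.0
  SP5:
    zone: atrial
    k: 8.075
    a1: 0.1
    a2: 0.1
    mu1: 0.022625
    mu2: 0.3
    eps0: 0.075
    ct: 300.0
  SP6:
    zone: atrial
    k: 8.075
    a1: 0.1
    a2: 0.1
    mu1: 0.022625
    mu2: 0.3
    eps0: 0.075
    ct: 300.0
  SP7:
    zone: atrial
    k: 7.46875
    a1: -0.0005
    a2: 0.295
    mu1: 0.022625
    mu2: 0.3
    eps0: 0.02
    ct: 300.0
  SP8:
    zone: atrial
    k: 8.0
    a1: -0.032856304932
    a2: 0.15
    mu1: 0.1
    mu2: 0.3
    eps0: 0.06475
    ct: 300.0
  SP9:
    zone: atrial
    k: 7.46875
    a1: -0.0005
    a2: 0.295
    mu1: 0.022625
    mu2: 0.3
    eps0: 0.02
    ct: 300.0
  SP10:
    zone: atrial
    k: 7.46875
    a1: -0.0005
    a2: 0.295
    mu1: 0.022625
    mu2: 0.3
    eps0: 0.02
    ct: 300.0
  AM*:
    zone: atrial
    k: 8.0
    a1: 0.071
    a2: 0.071
    mu1: 0.1
    mu2: 0.3
    eps0: 0.08
    ct: 300.0
junctions:
- from: SN
  to: PS1
  d: 48.739234613906
  alpha: 1.0
- from: PS1
  to: PS2
  d: 40.616028844922
  alpha: 1.0
- from: PS2
  to: PS3
  d: 44.677631729414
  alpha: 1.0
- from: PS3
  to: AM1
  d: 64.985646151875
  alpha: 1.0
- from: AM1
  to: AM2
  d: 230.0
  alpha: 1.0
- from: AM2
  to: AM3
  d: 230.0
  alpha: 1.0
- from: AM3
  to: FP1
  d: 60.565268114578
  alpha: 0.85
- from: FP1
  to: FP2
  d: 65.640401182475
  alpha: 0.676875
- from: FP2
  to: FP3
  d: 69.966491762087
  alpha: 0.676875
- from: FP3
  to: FP4
  d: 74.2925823417
  alpha: 0.676875
- from: FP4
  to: FP5
  d: 78.618672921313
  alpha: 0.676875
- from: FP5
  to: FP6
  d: 82.944763500925
  alpha: 0.676875
- from: FP6
  to: FP7
  d: 87.270854080538
  alpha: 0.676875
- from: FP7
  to: FP8
  d: 91.596944660151
  alpha: 0.676875
- from: FP8
  to: PB
  d: 77.22190980524
  alpha: 0.65
- from: PB
  to: HB1
  d: 53.458006393675
  alpha: 0.65
- from: HB1
  to: HB2
  d: 53.458006393675
  alpha: 0.65
- from: HB2
  to: HB3
  d: 53.458006393675
  alpha: 0.8
- from: HB3
  to: HB4
  d: 53.458006393675
  alpha: 1.0
- from: HB4
  to: HB5
  d: 53.458006393675
  alpha: 1.0
- from: HB5
  to: HB6
  d: 53.458006393675
  alpha: 1.0
- from: AM3
  to: SP1
  d: 108.5
  alpha: 0.61875
- from: SP1
  to: SP2
  d: 58.0
  alpha: 0.7075
- from: SP2
  to: SP3
  d: 58.0
  alpha: 0.7075
- from: SP3
  to: SP4
  d: 58.0
  alpha: 0.7075
- from: SP4
  to: SP5
  d: 58.0
  alpha: 0.7075
- from: SP5
  to: SP6
  d: 58.0
  alpha: 0.7075
- from: SP6
  to: SP7
  d: 58.0
  alpha: 0.4225
- from: SP7
  to: SP8
  d: 58.0
  alpha: 0.4225
- from: SP8
  to: SP9
  d: 85.0
  alpha: 0.4225
- from: SP9
  to: SP10
  d: 75.0
  alpha: 0.4225
- from: SP10
  to: PB
  d: 109.375
  alpha: 0.79125
- from: AM*
  to: AM3
  d: 230.0
  alpha: 1.0
entry:
  antero: AM1
  retro: HB1
  af: AM*
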