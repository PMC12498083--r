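# Default ISAR model catalogue: 20 smooth forms + 4 piecewise threshold
# forms. Remove or add names to change membership; optional per-parameter
# bound overrides may be given under `bounds:`.
models:
  - linear
  - power
  - powerR
  - exponential
  - kobayashi
  - p1
  - p2
  - negexpo
  - monod
  - rational
  - asymp
  - chapman
  - gompertz
  - extreme
  - weibull3
  - weibull4
  - mmf
  - lomolino
  - betap
  - heleg
  - pw_cont1
  - pw_zslope1
  - pw_discont1
  - pw_cont2
# bounds:
#   power:
#     z: [0.0, 2.0]
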