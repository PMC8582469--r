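# material compositions by mass fraction; ICRP/ICRU tissue reports,
# NIST liquid water and dry air, engineering alloys
material Water 1
  H 0.111894
  O 0.888106
material Air 0.0012048
  C 0.000124
  N 0.755268
  O 0.231781
  Ar 0.012827
material Lung 0.26
  H 0.103
  C 0.105
  N 0.031
  O 0.749
  Na 0.002
  P 0.002
  S 0.003
  Cl 0.003
  K 0.002
material SoftTissue 1
  H 0.104472
  C 0.23219
  N 0.02488
  O 0.630268
  Na 0.00113
  Mg 0.00013
  P 0.00133
  S 0.00199
  Cl 0.00134
  K 0.00199
  Ca 0.00023
  Fe 5e-05
material ProstateICRU 1.04
  H 0.105
  C 0.089
  N 0.025
  O 0.774
  Na 0.002
  P 0.001
  S 0.002
  K 0.002
material CorticalBone 1.92
  H 0.047234
  C 0.14433
  N 0.04199
  O 0.446196
  Mg 0.0022
  P 0.10497
  S 0.00315
  Ca 0.20993
material Titanium 4.506
  Ti 1
material Silver 10.5
  Ag 1
material Gold 19.32
  Au 1
material Alumina 3.97
  Al 0.529251
  O 0.470749
material Steel316L 8
  C 0.0003
  Si 0.01
  Mn 0.02
  Cr 0.17
  Fe 0.6547
  Ni 0.12
  Mo 0.025
material SteelCable 5.6
  C 0.0003
  Si 0.01
  Mn 0.02
  Cr 0.17
  Fe 0.6547
  Ni 0.12
  Mo 0.025
material Iridium 22.42
  Ir 1
material Nitinol 6.45
  Ni 0.556
  Ti 0.444
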