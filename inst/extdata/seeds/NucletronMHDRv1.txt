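# Nucletron microSelectron mHDR-v1 (classic) HDR Ir-192 source
# Dimensions per the published consensus description (Daskalov, Loeffler,
# Williamson, Med Phys 25 (1998) 2200):
#   iridium core 0.6 mm diameter x 3.5 mm; AISI 316L stainless capsule
#   1.1 mm OD with rounded distal tip, active-end to tip distance 0.35 mm;
#   stainless drive-cable stub on the proximal (-Z) side, modelled as a
#   5 mm cylinder of reduced-density woven steel.
id: NucletronMHDRv1
nuclide: Ir192
active_length_mm: 3.5
active_component: core
active_mode: volume
# name kind radius_mm half_len_mm r2_mm z_offset_mm material role
core cylinder 0.30 1.75 0 0 Iridium active
capsule capsule 0.55 1.75 0 -0.20 Steel316L capsule
cable cylinder 0.55 2.50 0 -5.00 SteelCable cable
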