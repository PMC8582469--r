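# Nucletron microSelectron mPDR-v2 PDR Ir-192 source
# Dimensions per the published consensus description (Karaiskos et al.,
# Med Phys 30 (2003) 9, and the HEBD source registry):
#   iridium core 0.6 mm diameter x 1.0 mm; AISI 316L capsule 1.1 mm OD
#   with rounded tip, active-end to tip distance 0.6 mm; proximal
#   stainless cable stub.
id: NucletronMPDRv2
nuclide: Ir192
active_length_mm: 1.0
active_component: core
active_mode: volume
# name kind radius_mm half_len_mm r2_mm z_offset_mm material role
core cylinder 0.30 0.50 0 0 Iridium active
capsule capsule 0.55 0.75 0 -0.20 Steel316L capsule
cable cylinder 0.55 2.50 0 -4.00 SteelCable cable
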