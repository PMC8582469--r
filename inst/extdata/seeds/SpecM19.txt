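# SPEC Industries M-19 HDR Ir-192 source
# Approximate published description (HEBD source registry): iridium core
# 0.59 mm diameter x 3.5 mm inside a stainless capsule of 1.1 mm OD with
# rounded tip and proximal cable. Encoded here with the same capsule
# construction as the classic microSelectron HDR design; marked approximate
# because a full consensus geometry paper is not reproduced datum-by-datum.
id: SpecM19
nuclide: Ir192
active_length_mm: 3.5
active_component: core
active_mode: volume
# name kind radius_mm half_len_mm r2_mm z_offset_mm material role
core cylinder 0.295 1.75 0 0 Iridium active
capsule capsule 0.55 1.75 0 -0.20 Steel316L capsule
cable cylinder 0.55 2.50 0 -5.00 SteelCable cable
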