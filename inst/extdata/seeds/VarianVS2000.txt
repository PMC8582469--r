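# Varian VariSource VS2000 HDR Ir-192 source
# Dimensions per the published consensus description (Angelopoulos et al.,
# Med Phys 27 (2000) 2521, and the HEBD source registry):
#   two abutting iridium wires, together 0.34 mm diameter x 5.0 mm active;
#   nitinol (Ni-Ti) capsule 0.59 mm OD with hemispherical tip, active-end
#   to tip distance ~1.0 mm; nitinol cable stub on the proximal side.
id: VarianVS2000
nuclide: Ir192
active_length_mm: 5.0
active_component: core
active_mode: volume
# name kind radius_mm half_len_mm r2_mm z_offset_mm material role
core cylinder 0.17 2.50 0 0 Iridium active
capsule capsule 0.295 3.00 0 0.205 Nitinol capsule
cable cylinder 0.295 2.50 0 -5.59 Nitinol cable
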