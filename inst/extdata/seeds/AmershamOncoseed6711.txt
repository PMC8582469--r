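# Amersham Health OncoSeed 6711, LDR I-125 seed
# Dimensions per the published consensus description of the 6711
# (AAPM TG-43U1 report; Dolan et al., Med Phys 33 (2006) 4675):
#   silver rod 0.5 mm diameter x 3.0 mm, radioactive AgI layer on the rod
#   surface; titanium capsule 0.8 mm OD, 4.5 mm long, 0.05 mm wall,
#   rounded (hemispherical) end welds; interior filled with air.
id: AmershamOncoseed6711
nuclide: I125
active_length_mm: 3.0
active_component: core
active_mode: surface
# components innermost -> outermost
# name kind radius_mm half_len_mm r2_mm z_offset_mm material role
core cylinder 0.25 1.5 0 0 Silver active
cavity capsule 0.35 1.85 0 0 Air interior
capsule capsule 0.40 1.85 0 0 Titanium capsule
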