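# Bebig/Theragenics IsoSeed I25.S06, LDR I-125 seed
# Dimensions per the published consensus description (AAPM TG-43U1 supplement;
# Hedtjarn, Carlsson, Williamson, Med Phys 27 (2000) 1076):
#   gold X-ray marker 0.17 mm diameter x 3.5 mm at the centre of an
#   alumina (Al2O3) ceramic cylinder 0.6 mm diameter x 3.5 mm carrying the
#   I-125 activity through its volume; titanium capsule 0.8 mm OD x 4.5 mm,
#   0.05 mm wall, rounded ends, air-filled interior.
id: BebigIsoseedI25S06
nuclide: I125
active_length_mm: 3.5
active_component: ceramic
active_mode: volume
# name kind radius_mm half_len_mm r2_mm z_offset_mm material role
marker cylinder 0.085 1.75 0 0 Gold marker
ceramic cylinder 0.30 1.75 0 0 Alumina active
cavity capsule 0.35 1.85 0 0 Air interior
capsule capsule 0.40 1.85 0 0 Titanium capsule
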