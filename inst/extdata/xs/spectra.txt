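# radionuclide photon line spectra, energies keV,
# emission probabilities per decay (published decay tables);
# Ir-192 beta continuum omitted (photon-only transport)
nuclide I125 5
  27.2020 0.406
  27.4720 0.757
  30.9440 0.202
  31.7040 0.0439
  35.4920 0.0668
nuclide Ir192 18
  65.1220 0.0263
  66.8310 0.0449
  75.7490 0.0205
  136.3430 0.00199
  201.3110 0.00473
  205.7940 0.0334
  283.2670 0.00269
  295.9570 0.287
  308.4550 0.297
  316.5060 0.8286
  374.4850 0.00727
  416.4690 0.0067
  468.0690 0.4781
  484.5750 0.0319
  489.0600 0.00438
  588.5810 0.0452
  604.4110 0.082
  612.4620 0.0534
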