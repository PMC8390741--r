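{
  "_comment": "SYNTHETIC illustrative sphere-model self-dose coupling table for tumor dosimetry: Theta(m) in kg mGy/(MBq s) versus sphere mass in kg. The absorbed fraction rises toward 1 with sphere size for Lu-177 betas, so Theta approaches the equilibrium dose constant 2.35e-5 at large masses.",
  "mass_kg": [0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1.0, 5.0, 10.0],
  "theta":   [1.80e-5, 1.95e-5, 2.05e-5, 2.18e-5, 2.22e-5, 2.28e-5, 2.30e-5, 2.33e-5, 2.35e-5]
}
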