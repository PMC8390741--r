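{
  "_comment": "SYNTHETIC stand-in dose-factor table. Self dose factors are Theta/m with Theta = 2.35e-5 kg mGy/(MBq s), the Lu-177 beta equilibrium dose constant with absorbed fraction ~1; organ masses are nominal phantom masses (kg). Cross factors are illustrative small values. theta_bm_bm is in mGy per MBq h/cc of integrated blood concentration; theta_bm_rm in mGy per MBq h/kg of integrated remainder specific activity. Not a redistribution of any published phantom compilation.",
  "adult_male": {
    "entries": [
      {"source": "kidneys",   "target": "kidneys",   "df_mGy_per_MBq_s": 7.581e-5},
      {"source": "liver",     "target": "liver",     "df_mGy_per_MBq_s": 1.306e-5},
      {"source": "spleen",    "target": "spleen",    "df_mGy_per_MBq_s": 1.306e-4},
      {"source": "remainder", "target": "remainder", "df_mGy_per_MBq_s": 3.917e-7},
      {"source": "liver",     "target": "kidneys",   "df_mGy_per_MBq_s": 6.0e-8},
      {"source": "spleen",    "target": "kidneys",   "df_mGy_per_MBq_s": 9.0e-8},
      {"source": "kidneys",   "target": "liver",     "df_mGy_per_MBq_s": 6.0e-8},
      {"source": "spleen",    "target": "liver",     "df_mGy_per_MBq_s": 2.5e-8},
      {"source": "kidneys",   "target": "spleen",    "df_mGy_per_MBq_s": 9.0e-8},
      {"source": "liver",     "target": "spleen",    "df_mGy_per_MBq_s": 2.5e-8}
    ],
    "theta_bm_bm": 150,
    "theta_bm_rm": 0.008
  },
  "adult_female": {
    "entries": [
      {"source": "kidneys",   "target": "kidneys",   "df_mGy_per_MBq_s": 8.545e-5},
      {"source": "liver",     "target": "liver",     "df_mGy_per_MBq_s": 1.679e-5},
      {"source": "spleen",    "target": "spleen",    "df_mGy_per_MBq_s": 1.567e-4},
      {"source": "remainder", "target": "remainder", "df_mGy_per_MBq_s": 4.700e-7},
      {"source": "liver",     "target": "kidneys",   "df_mGy_per_MBq_s": 7.0e-8},
      {"source": "spleen",    "target": "kidneys",   "df_mGy_per_MBq_s": 1.0e-7},
      {"source": "kidneys",   "target": "liver",     "df_mGy_per_MBq_s": 7.0e-8},
      {"source": "spleen",    "target": "liver",     "df_mGy_per_MBq_s": 3.0e-8},
      {"source": "kidneys",   "target": "spleen",    "df_mGy_per_MBq_s": 1.0e-7},
      {"source": "liver",     "target": "spleen",    "df_mGy_per_MBq_s": 3.0e-8}
    ],
    "theta_bm_bm": 165,
    "theta_bm_rm": 0.009
  }
}
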