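{
  "label": "d731n_d731n",
  "calibration_notes": "Synthetic 6-state gating model for the two-copy mutant tri-heteromer (D731N/D731N): glutamate EC50 ~30.5 mM, saturating open probability 0.064, MK-801 onset 1/tau ~0.066 s^-1 at 0.2 uM and EC50 glutamate, proton ratio (pH 6.8/7.6) ~33%. Zinc/Mg fields are mutant-like placeholders (not measured for tri-heteromers). Not fitted to any recording.",
  "calibration_targets": {
    "glutamate_ec50_uM": 30469,
    "popen_saturating": 0.064,
    "inv_tau_mk801_per_s": 0.066
  },
  "k_on_glu": 2.4788e-06,
  "k_off_glu": 0.035,
  "beta": 0.03655,
  "alpha": 0.5,
  "k_des": 0.0018495,
  "k_res": 0.027,
  "k_block_mk": 0.010307,
  "glycine_ec50": 2.0,
  "glycine_hill": 1.4,
  "proton_ic50_pH": 7.3,
  "proton_hill": 1.08,
  "zinc_ic50": 20,
  "zinc_hill": 1.0,
  "zinc_residual": 0.381,
  "mg_ic50_at_v": 25,
  "mg_v_ref": -60,
  "mg_v_slope": 17,
  "n_channels": 2500,
  "gamma": 50,
  "v_rev": 0,
  "gamma_mtsea_ratio": 0.70,
  "popen_after_mtsea": 1.0
}
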