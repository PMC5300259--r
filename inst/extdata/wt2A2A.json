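{
  "label": "wt2A2A",
  "calibration_notes": "Synthetic 6-state gating model for the tri-heteromeric wild-type control (C1/C2-tagged 2A/2A): glutamate EC50 5.7 uM, saturating open probability 0.370, MK-801 onset 1/tau ~0.405 s^-1 at 0.2 uM and EC50 glutamate, proton ratio (pH 6.8/7.6) ~59%. Desensitization and deactivation tempo inherited from the wild-type di-heteromer (not separately reported for tri-heteromers). Zinc/Mg fields are wild-type-like placeholders (not measured for tri-heteromers). Not fitted to any recording.",
  "calibration_targets": {
    "glutamate_ec50_uM": 5.7,
    "popen_saturating": 0.370,
    "inv_tau_mk801_per_s": 0.405
  },
  "k_on_glu": 0.0028255,
  "k_off_glu": 0.0242,
  "beta": 0.2973,
  "alpha": 0.1527,
  "k_des": 0.0060216,
  "k_res": 0.0026,
  "k_block_mk": 0.010947,
  "glycine_ec50": 1.3,
  "glycine_hill": 1.4,
  "proton_ic50_pH": 6.8,
  "proton_hill": 0.93,
  "zinc_ic50": 87,
  "zinc_hill": 1.0,
  "zinc_residual": 0.5356,
  "mg_ic50_at_v": 31,
  "mg_v_ref": -60,
  "mg_v_slope": 17,
  "n_channels": 3000,
  "gamma": 50,
  "v_rev": 0,
  "gamma_mtsea_ratio": 0.70,
  "popen_after_mtsea": 1.0
}
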