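{
  "label": "d731n_2a",
  "calibration_notes": "Synthetic 6-state gating model for the single-copy mutant tri-heteromer (D731N/2A), calibrated as its own parameter set (not derived from the homomeric models): glutamate EC50 ~6.45 mM, saturating open probability 0.249, MK-801 onset 1/tau ~0.273 s^-1 at 0.2 uM and EC50 glutamate, proton ratio (pH 6.8/7.6) ~37%. Zinc/Mg fields are interpolated placeholders (not measured for tri-heteromers). Not fitted to any recording.",
  "calibration_targets": {
    "glutamate_ec50_uM": 6451,
    "popen_saturating": 0.249,
    "inv_tau_mk801_per_s": 0.273
  },
  "k_on_glu": 5.86e-06,
  "k_off_glu": 0.03,
  "beta": 0.1656,
  "alpha": 0.3,
  "k_des": 0.00665,
  "k_res": 0.01,
  "k_block_mk": 0.010965,
  "glycine_ec50": 2.1,
  "glycine_hill": 1.4,
  "proton_ic50_pH": 7.3,
  "proton_hill": 1.0,
  "zinc_ic50": 50,
  "zinc_hill": 1.0,
  "zinc_residual": 0.45,
  "mg_ic50_at_v": 28,
  "mg_v_ref": -60,
  "mg_v_slope": 17,
  "n_channels": 3000,
  "gamma": 50,
  "v_rev": 0,
  "gamma_mtsea_ratio": 0.70,
  "popen_after_mtsea": 1.0
}
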