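{
  "label": "wt2A",
  "calibration_notes": "Synthetic 6-state gating model calibrated so closed-form equilibrium quantities match the di-heteromeric wild-type GluN1/GluN2A characterization: glutamate EC50 3.7 uM, saturating open probability 0.278, steady/peak ratio ~0.56, fast/slow deactivation ~41/384 ms (tau_w ~72 ms), 10-90% rise ~5 ms, MK-801 onset 1/tau ~0.334 s^-1 at 0.2 uM and EC50 glutamate, proton ratio (pH 6.8/7.6) ~54%, zinc IC50 87 nM with ~36% inhibition at 300 nM, Mg IC50 31 uM at -60 mV. Not fitted to any recording; all values are model-derived.",
  "calibration_targets": {
    "glutamate_ec50_uM": 3.7,
    "popen_saturating": 0.278,
    "iss_over_ipeak": 0.56,
    "tau_w_ms": 72,
    "inv_tau_mk801_per_s": 0.334,
    "peak_density_pA_per_pF": 235
  },
  "k_on_glu": 0.005777,
  "k_off_glu": 0.0242,
  "beta": 0.2234,
  "alpha": 0.2266,
  "k_des": 0.004056,
  "k_res": 0.0026,
  "k_block_mk": 0.012013,
  "glycine_ec50": 1.1,
  "glycine_hill": 1.4,
  "proton_ic50_pH": 6.8,
  "proton_hill": 1.37,
  "zinc_ic50": 87,
  "zinc_hill": 1.0,
  "zinc_residual": 0.5356,
  "mg_ic50_at_v": 31,
  "mg_v_ref": -60,
  "mg_v_slope": 17,
  "n_channels": 3750,
  "gamma": 50,
  "v_rev": 0,
  "gamma_mtsea_ratio": 0.70,
  "popen_after_mtsea": 1.0
}
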