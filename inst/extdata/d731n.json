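{
  "label": "d731n",
  "calibration_notes": "Synthetic 6-state gating model calibrated to the di-heteromeric GluN1/GluN2A(D731N) characterization: glutamate EC50 ~13.7 mM, saturating open probability 0.046, steady/peak ratio ~0.94, fast/slow deactivation ~15/37 ms (tau_w ~18 ms), 10-90% rise ~17 ms, MK-801 onset 1/tau ~0.056 s^-1 at 0.2 uM and EC50 glutamate, proton ratio (pH 6.8/7.6) ~34%, zinc IC50 20 nM with ~58% inhibition at 300 nM, Mg IC50 25 uM at -60 mV, peak density ~5 pA/pF. Not fitted to any recording; all values are model-derived.",
  "calibration_targets": {
    "glutamate_ec50_uM": 13655,
    "popen_saturating": 0.046,
    "iss_over_ipeak": 0.94,
    "tau_w_ms": 18,
    "inv_tau_mk801_per_s": 0.056,
    "peak_density_pA_per_pF": 5.1
  },
  "k_on_glu": 5.6259e-06,
  "k_off_glu": 0.035,
  "beta": 0.02573,
  "alpha": 0.5,
  "k_des": 0.0018144,
  "k_res": 0.027,
  "k_block_mk": 0.012174,
  "glycine_ec50": 1.7,
  "glycine_hill": 1.4,
  "proton_ic50_pH": 7.3,
  "proton_hill": 1.05,
  "zinc_ic50": 20,
  "zinc_hill": 1.0,
  "zinc_residual": 0.381,
  "mg_ic50_at_v": 25,
  "mg_v_ref": -60,
  "mg_v_slope": 17,
  "n_channels": 1830,
  "gamma": 50,
  "v_rev": 0,
  "gamma_mtsea_ratio": 0.70,
  "popen_after_mtsea": 1.0
}
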