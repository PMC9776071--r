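{
  "description": "Published reference measurements from a three-patient carotid endarterectomy FSI case study: plaque component volumes and thinnest fibrous cap from multi-contrast MRI segmentation, TAWSS statistics over the apex-anchored 17 mm ICA region of interest, and peak-systole maximum principal stress with 13 mm ROI statistics. Used to validate the package's comparison arithmetic; the FSI magnitudes themselves are not reproduced by the surrogates.",
  "patients": {
    "patient1": {
      "stenosis_percent": 81,
      "calcification_volume_mm3": 3.44,
      "lipid_volume_mm3": 42.79,
      "thinnest_cap_mm": 0.729,
      "tawss_mean_pa": 5.45,
      "tawss_sd_pa": 6.44,
      "stress_max_kpa": 133.1,
      "stress_roi_mean_kpa": 22.221,
      "stress_roi_sd_kpa": 16.579
    },
    "patient2": {
      "stenosis_percent": 83,
      "calcification_volume_mm3": 77.38,
      "lipid_volume_mm3": 48.59,
      "thinnest_cap_mm": 1.186,
      "tawss_mean_pa": 14.62,
      "tawss_sd_pa": 13.72,
      "stress_max_kpa": 116.9,
      "stress_roi_mean_kpa": 13.098,
      "stress_roi_sd_kpa": 20.378
    },
    "patient3": {
      "stenosis_percent": 82,
      "calcification_volume_mm3": 10.43,
      "lipid_volume_mm3": 236.79,
      "thinnest_cap_mm": 0.676,
      "tawss_mean_pa": 6.99,
      "tawss_sd_pa": 6.34,
      "stress_max_kpa": 127.4,
      "stress_roi_mean_kpa": 21.075,
      "stress_roi_sd_kpa": 17.391
    }
  },
  "printed_comparisons": [
    {"id": "calcification_fold_p2_vs_p1", "quantity": "calcification_volume", "case_a": "patient2", "case_b": "patient1", "type": "fold", "printed": 22.4, "digits": 1},
    {"id": "calcification_fold_p2_vs_p3", "quantity": "calcification_volume", "case_a": "patient2", "case_b": "patient3", "type": "fold", "printed": 7.4, "digits": 1},
    {"id": "lipid_fold_p3_vs_p1", "quantity": "lipid_volume", "case_a": "patient3", "case_b": "patient1", "type": "fold", "printed": 5.5, "digits": 1},
    {"id": "lipid_fold_p3_vs_p2", "quantity": "lipid_volume", "case_a": "patient3", "case_b": "patient2", "type": "fold", "printed": 4.87, "digits": 2},
    {"id": "tawss_fold_p2_vs_p1", "quantity": "tawss_mean", "case_a": "patient2", "case_b": "patient1", "type": "fold", "printed": 2.7, "digits": 1},
    {"id": "tawss_fold_p2_vs_p3", "quantity": "tawss_mean", "case_a": "patient2", "case_b": "patient3", "type": "fold", "printed": 2.1, "digits": 1},
    {"id": "stress_max_pctdiff_p1_vs_p2", "quantity": "stress_max", "case_a": "patient1", "case_b": "patient2", "type": "pct_diff", "printed": 13.8, "digits": 1},
    {"id": "stress_max_pctdiff_p3_vs_p2", "quantity": "stress_max", "case_a": "patient3", "case_b": "patient2", "type": "pct_diff", "printed": 8.9, "digits": 1}
  ]
}
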