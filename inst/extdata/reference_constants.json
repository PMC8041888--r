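{
  "forest_area_ha": 1464000,
  "population": 161356039,
  "national_accuracy_pct": 91.5,
  "gcp_points": 8200,
  "gcp_holdout_points": 400,
  "dtm_rmse_m": 1.2,
  "calibration_plots": 9499,
  "validation_plots": 3024,
  "validation_plot_outliers": 12,
  "mae_before_m": 3.38,
  "mae_after_m": 1.41,
  "min_tree_height_m": 2.19,
  "validation_points_per_class_per_division": 500,
  "validation_buffer_m": 10
}
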