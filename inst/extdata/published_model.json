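{
  "schema_version": "1.0",
  "structure": "ergodic",
  "comment": "Parameter set reported from a 500-event field study of the lane-changing process (25 drivers, urban network driving). The contribution matrix is the printed per-feature emission-share summary over (fixation duration, saccade range, SDNN, average speed); it is not a Gaussian-mixture emission parameterisation and is consumed as a summary only.",
  "pi": [0.8584, 0.1416],
  "A": [[0.7529, 0.2471], [0.2537, 0.7463]],
  "printed_contribution_matrix": [[0.1369, 0.2536, 0.4359, 0.1736], [0.3726, 0.2108, 0.1903, 0.2263]],
  "feature_names": ["fixation_duration_ms", "saccade_range_deg", "sdnn_ms", "avg_speed_kmh"],
  "state_labels": ["safe", "dangerous"]
}
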