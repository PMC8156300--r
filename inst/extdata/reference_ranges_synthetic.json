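{
  "comment": "Synthetic placeholder healthy reference values by age band. Physiologically plausible scales only; replace with means from a real healthy reference population before clinical use.",
  "deviation_fraction": 0.2,
  "etco2_range": [35, 45],
  "spo2_min": 95,
  "ages": [
    {"age_min": 0,  "age_max": 1,   "rr_mean": 40, "rc_percent_mean": 45, "lbi_mean": 1.15, "phase_mean": 15},
    {"age_min": 1,  "age_max": 3,   "rr_mean": 28, "rc_percent_mean": 47, "lbi_mean": 1.12, "phase_mean": 12},
    {"age_min": 3,  "age_max": 6,   "rr_mean": 24, "rc_percent_mean": 48, "lbi_mean": 1.10, "phase_mean": 10},
    {"age_min": 6,  "age_max": 12,  "rr_mean": 20, "rc_percent_mean": 50, "lbi_mean": 1.08, "phase_mean": 10},
    {"age_min": 12, "age_max": 18,  "rr_mean": 16, "rc_percent_mean": 50, "lbi_mean": 1.06, "phase_mean": 8},
    {"age_min": 18, "age_max": 120, "rr_mean": 14, "rc_percent_mean": 50, "lbi_mean": 1.05, "phase_mean": 8}
  ]
}
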