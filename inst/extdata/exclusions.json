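{
  "excluded_code_prefixes": ["194.0", "227.0", "255.6", "405"],
  "ckd_egfr_threshold": 30,
  "ckd_window_days_after_index": 183,
  "hf_ef_threshold": 35,
  "hf_window_days": 365
}
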