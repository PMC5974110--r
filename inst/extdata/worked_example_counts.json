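{
  "comment": "Worked-example gene counts for the report subcommand: printed list sizes from the emulated study, used as inputs to the package's set-algebra operations.",
  "overlaps": [
    {"id": "up_common_glucose_limited_vs_stationary", "subset": 10, "total": 160},
    {"id": "cobB_upper_shared_with_ratio_list", "subset": 3, "total": 22},
    {"id": "hypothetical_in_negative_interaction", "subset": 24, "total": 38}
  ],
  "ratios": [
    {"id": "cobB_vs_patZ_prevalence", "a": 50, "b": 14}
  ],
  "spurious_by_phase": {
    "false_negative": {"exponential": 22, "stationary": 47},
    "false_positive": {"exponential": 191, "stationary": 21}
  }
}
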