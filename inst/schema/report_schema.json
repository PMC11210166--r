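{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mrpipe analysis report",
  "type": "object",
  "required": [
    "config",
    "package_version",
    "provenance",
    "strength",
    "strength_summary",
    "harmonization",
    "model",
    "estimates",
    "run_info"
  ],
  "properties": {
    "config": {"type": "object"},
    "package_version": {"type": "string"},
    "provenance": {
      "description": "per-stage filter log; counts telescope from input to estimation"
    },
    "strength": {"description": "per-variant R2/F table"},
    "strength_summary": {"type": "object"},
    "harmonization": {"description": "per-variant action/reason table"},
    "model": {
      "type": "object",
      "required": ["rule", "chosen", "q_pvalue"]
    },
    "estimates": {"description": "one row per estimator, both scales"},
    "q_test": {"type": "object"},
    "egger_intercept": {"type": "object"},
    "presso": {"type": "object"},
    "loo": {"description": "leave-one-out table, full-set row last"},
    "plot_data": {"type": "object"},
    "run_info": {
      "type": "object",
      "description": "timestamps and host info quarantined here so the rest of the report is diffable"
    }
  }
}
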