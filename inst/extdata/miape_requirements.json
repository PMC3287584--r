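{
  "comment": "Minimum-information field requirements per experiment type. Dotted paths resolve into the experiment record; edit to tighten or relax reporting requirements.",
  "all": ["performed_by", "date", "samples", "protocol"],
  "MS": ["conditions.instrument", "conditions.ionization", "conditions.analyzer_mode"],
  "GEL2D": ["conditions.strip_pi_low", "conditions.strip_pi_high", "conditions.gel_percent", "conditions.stain"],
  "LC": ["conditions.instrument", "conditions.column", "conditions.solvent_a"],
  "PREP": []
}
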