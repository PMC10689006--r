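{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tbiconn pipeline report",
  "type": "object",
  "required": ["software", "seed", "config", "subjects"],
  "properties": {
    "software": {
      "type": "object",
      "required": ["package", "version"]
    },
    "seed": { "type": "integer" },
    "config": { "type": "object" },
    "subjects": {
      "type": "object",
      "required": ["subject_id", "group", "persistent_low_md_mm3"]
    },
    "low_md_parcels": { "type": "array", "items": { "type": "string" } },
    "group_mean_congruence": { "type": ["number", "null"] },
    "contrast_summary": { "type": ["object", "null"] }
  }
}
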