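{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "candidate_report",
  "type": "object",
  "required": ["policy", "ranked", "excluded", "n_ranked"],
  "properties": {
    "policy": {
      "type": "object",
      "required": ["require_permeable", "exclude_pgp", "sort_keys"],
      "properties": {
        "require_permeable": {"type": "boolean"},
        "exclude_pgp": {"type": "boolean"},
        "require_safety_window": {"type": "boolean"},
        "sort_keys": {"type": "array", "items": {"type": "string"}}
      }
    },
    "ranked": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rank", "complex", "drug"],
        "properties": {
          "rank": {"type": "integer", "minimum": 1},
          "complex": {"type": "string"},
          "drug": {"type": "string"},
          "protein_rmsd_mean": {"type": "number"},
          "hbond_mean": {"type": ["number", "null"]},
          "logbb": {"type": "number"}
        }
      }
    },
    "excluded": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["complex", "drug", "reason"]
      }
    },
    "n_ranked": {"type": "integer", "minimum": 0},
    "provenance": {"type": "string"}
  }
}
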