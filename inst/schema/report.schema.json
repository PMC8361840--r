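{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "evidemcda pipeline report",
  "type": "object",
  "required": ["meta", "aggregated", "normalized_weights", "contributions", "values", "ranking"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["policy", "seed", "n_panelists", "weight_denominator", "included_criteria", "timestamp"],
      "properties": {
        "package": {"type": "string"},
        "policy": {"type": "string"},
        "seed": {"type": "integer"},
        "digits": {"type": "integer"},
        "n_panelists": {"type": "integer"},
        "weight_denominator": {"type": "number"},
        "included_criteria": {"type": "array"},
        "unscored_criteria": {"type": "array"},
        "unweighted_criteria": {"type": "array"},
        "timestamp": {"type": "string"}
      }
    },
    "aggregated": {
      "type": "object",
      "required": ["weights", "scores"],
      "properties": {
        "weights": {"type": "array"},
        "scores": {"type": "array"}
      }
    },
    "normalized_weights": {"type": "array"},
    "contributions": {"type": "array"},
    "values": {"type": "array"},
    "ranking": {"type": "array"},
    "stability": {
      "type": "object",
      "required": ["n_draws", "seed", "rank_probability", "summary"],
      "properties": {
        "n_draws": {"type": "integer"},
        "seed": {"type": "integer"},
        "rank_probability": {"type": "array"},
        "summary": {"type": "array"}
      }
    }
  }
}
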