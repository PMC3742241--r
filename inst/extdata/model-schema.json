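{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "consensus_pharmacophore",
  "type": "object",
  "required": ["meta", "features", "excluded_volumes"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["n_complexes", "threshold", "provenance"],
      "properties": {
        "n_complexes": {"type": "integer", "minimum": 1},
        "threshold": {"type": "number", "minimum": 0, "maximum": 100},
        "provenance": {"type": "array", "items": {"type": "string"}}
      }
    },
    "features": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "kind", "center", "tolerance"],
        "properties": {
          "id": {"type": "string"},
          "kind": {"enum": ["HBD", "HBA", "HYD", "POS", "NEG"]},
          "center": {
            "type": "array", "minItems": 3, "maxItems": 3,
            "items": {"type": "number"}
          },
          "tolerance": {"type": "number", "exclusiveMinimum": 0},
          "count": {"type": "integer", "minimum": 1},
          "frequency": {"type": "integer", "minimum": 0, "maximum": 100}
        }
      }
    },
    "excluded_volumes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["center", "radius"],
        "properties": {
          "center": {
            "type": "array", "minItems": 3, "maxItems": 3,
            "items": {"type": "number"}
          },
          "radius": {"type": "number", "exclusiveMinimum": 0},
          "residue": {"type": "string"}
        }
      }
    }
  }
}
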