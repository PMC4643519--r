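{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cohortflow Sankey document",
  "type": "object",
  "required": ["meta", "nodes", "links"],
  "properties": {
    "meta": {
      "type": "object",
      "properties": {
        "generator": {"type": "string"},
        "entropy_mode": {"enum": ["shannon", "as-printed"]},
        "filter_threshold": {"type": ["number", "null"]},
        "crossings": {
          "type": "object",
          "properties": {"initial": {"type": "number"}, "final": {"type": "number"}}
        }
      }
    },
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "window", "label", "size", "x", "top", "color"],
        "properties": {
          "id": {"type": "string"},
          "window": {"type": "integer", "minimum": 1},
          "label": {"type": "string"},
          "size": {"type": "number", "minimum": 0},
          "x": {"type": "number"},
          "top": {"type": "number"},
          "color": {"type": "string", "pattern": "^#[0-9A-F]{6}$"}
        }
      }
    },
    "links": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "source", "target", "size", "probability", "color", "z"],
        "properties": {
          "id": {"type": "string"},
          "source": {"type": "string"},
          "target": {"type": "string"},
          "size": {"type": "number", "exclusiveMinimum": 0},
          "probability": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
          "entropy": {"type": "number"},
          "color": {"type": "array", "items": {"type": "string"}, "minItems": 2, "maxItems": 2},
          "z": {"type": "integer", "minimum": 0}
        }
      }
    },
    "highlight": {
      "type": "object",
      "properties": {
        "n_patients": {"type": "integer", "minimum": 0},
        "nodes": {"type": "object", "additionalProperties": {"type": "number"}},
        "links": {"type": "object", "additionalProperties": {"type": "number"}}
      }
    }
  }
}
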