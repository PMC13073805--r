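{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cavityfield run report",
  "type": "object",
  "required": ["entry", "n_inside", "n_kept", "percent_removed", "ellipsoid", "models"],
  "properties": {
    "entry": {"type": "string", "enum": ["trajectory", "grids", "control_points"]},
    "n_frames": {"type": ["integer", "null"]},
    "n_inside": {"type": "integer", "minimum": 1},
    "n_kept": {"type": "integer", "minimum": 0},
    "percent_removed": {"type": "number", "minimum": 0, "maximum": 100},
    "ellipsoid": {
      "type": "object",
      "required": ["center", "radii"],
      "properties": {
        "center": {"type": "array", "items": {"type": "number"}, "minItems": 3, "maxItems": 3},
        "radii": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}, "minItems": 3, "maxItems": 3},
        "dz_best": {"type": ["number", "null"]}
      }
    },
    "models": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["order", "coefficients", "r_squared"],
        "properties": {
          "order": {"type": "integer", "enum": [1, 2]},
          "coefficients": {"type": "object"},
          "r_squared": {"type": "number", "maximum": 1}
        }
      }
    },
    "field": {
      "type": ["object", "null"],
      "properties": {
        "volts_per_angstrom": {"type": "object"},
        "volts_per_nm": {"type": "object"}
      }
    },
    "keyword": {"type": ["string", "null"]},
    "versions": {"type": "object"}
  }
}
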