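{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cimplan run configuration",
  "type": "object",
  "required": ["plate_format", "protein", "screen"],
  "properties": {
    "plate_format": {"enum": ["mo132", "mo29", "foil100"]},
    "protein": {
      "type": "object",
      "required": ["conc_ug_ul"],
      "properties": {
        "conc_ug_ul": {"type": "number", "exclusiveMinimum": 0},
        "name": {"type": "string"}
      }
    },
    "screen": {
      "type": "object",
      "properties": {
        "grid": {
          "type": "object",
          "required": ["pH_min", "pH_max", "conc_min", "conc_max", "n_pH", "n_conc"],
          "properties": {
            "pH_min": {"type": "number"},
            "pH_max": {"type": "number"},
            "conc_min": {"type": "number", "minimum": 0},
            "conc_max": {"type": "number", "minimum": 0},
            "n_pH": {"type": "integer", "minimum": 2},
            "n_conc": {"type": "integer", "minimum": 2},
            "precipitant": {"type": "string"}
          }
        },
        "conditions": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["precipitant", "conc"],
            "properties": {
              "precipitant": {"type": "string"},
              "conc": {"type": "number", "minimum": 0},
              "pH": {"type": "number"}
            }
          }
        }
      },
      "anyOf": [{"required": ["grid"]}, {"required": ["conditions"]}]
    },
    "dilutions": {"type": "array", "items": {"type": "number", "minimum": 1}},
    "target_hydrations": {
      "type": "array",
      "items": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 100}
    },
    "phi": {"type": "number", "exclusiveMinimum": 0, "maximum": 1.1},
    "phase_map": {"type": "string"},
    "assay_csv": {"type": "string"},
    "seed": {"type": "integer"}
  }
}
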