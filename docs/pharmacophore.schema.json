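{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "pharmselect pharmacophore (schema pharmselect/1)",
  "type": "object",
  "required": ["schema", "id", "provenance", "receptor_id", "activity_class", "features"],
  "properties": {
    "schema": { "const": "pharmselect/1" },
    "id": { "type": "string" },
    "provenance": { "enum": ["SB", "LB"] },
    "receptor_id": { "type": "string" },
    "activity_class": { "enum": ["agonist", "antagonist"] },
    "source": { "type": "string", "description": "PDB code or cluster id" },
    "features": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["type", "x", "y", "z", "tolerance", "disabled", "optional"],
        "properties": {
          "type": { "enum": ["AR", "H", "HBA", "HBD", "PI", "NI", "MB"] },
          "x": { "type": "number" },
          "y": { "type": "number" },
          "z": { "type": "number" },
          "tolerance": { "type": "number", "exclusiveMinimum": 0 },
          "nx": { "type": ["number", "null"], "description": "unit ring normal, AR only" },
          "ny": { "type": ["number", "null"] },
          "nz": { "type": ["number", "null"] },
          "disabled": { "type": "boolean" },
          "optional": { "type": "boolean" }
        }
      }
    },
    "exclusions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["x", "y", "z", "radius", "manual"],
        "properties": {
          "x": { "type": "number" },
          "y": { "type": "number" },
          "z": { "type": "number" },
          "radius": { "type": "number", "exclusiveMinimum": 0 },
          "manual": { "type": "boolean" }
        }
      }
    }
  }
}
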