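{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Rule-base document",
  "description": "A condition catalogue plus clinical rules (6-element tuples). parse_rulebase() enforces these constraints and additionally validates cross-references: every id referenced by a rule exists in the catalogue with the matching kind, no id occupies two roles within one rule, and every rule premise is non-empty.",
  "type": "object",
  "required": ["conditions", "rules"],
  "additionalProperties": false,
  "properties": {
    "conditions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "kind": {"enum": ["clinical", "nonclinical"]},
          "label": {"type": "string"},
          "category": {"type": "string"},
          "codes": {"type": "array", "items": {"type": "string"}},
          "default_code": {
            "type": "integer", "minimum": 1,
            "description": "1-based index into codes of the most general code"
          }
        }
      }
    },
    "rules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "present_clinical": {"$ref": "#/$defs/idset"},
          "present_nonclinical": {"$ref": "#/$defs/idset"},
          "absent_clinical": {"$ref": "#/$defs/idset"},
          "absent_nonclinical": {"$ref": "#/$defs/idset"},
          "unions": {
            "type": "array",
            "items": {
              "type": "object",
              "additionalProperties": false,
              "minProperties": 1,
              "properties": {
                "clinical": {"$ref": "#/$defs/idset"},
                "nonclinical": {"$ref": "#/$defs/idset"}
              }
            }
          },
          "action": {"type": "string"}
        }
      }
    }
  },
  "$defs": {
    "idset": {
      "type": "array",
      "items": {"type": "string", "minLength": 1},
      "uniqueItems": true
    }
  }
}
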