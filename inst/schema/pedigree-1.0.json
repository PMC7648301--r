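{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "fhh-pedigree-1.0",
  "title": "Family health history pedigree interchange document",
  "description": "One document per proband: a self record plus relationship-coded relative records. The reference validator is the package parser; this schema documents the contract for external producers.",
  "type": "object",
  "required": ["proband"],
  "properties": {
    "format": {"const": "fhh-pedigree"},
    "version": {"type": "string"},
    "proband": {"$ref": "#/$defs/record"},
    "relatives": {"type": "array", "items": {"$ref": "#/$defs/record"}}
  },
  "$defs": {
    "record": {
      "type": "object",
      "required": ["relation"],
      "properties": {
        "relation": {
          "enum": ["self", "mother", "father", "sister", "brother",
                   "daughter", "son",
                   "maternal_grandmother", "maternal_grandfather",
                   "paternal_grandmother", "paternal_grandfather",
                   "maternal_aunt", "maternal_uncle",
                   "paternal_aunt", "paternal_uncle",
                   "niece", "nephew", "granddaughter", "grandson",
                   "maternal_half_sister", "maternal_half_brother",
                   "paternal_half_sister", "paternal_half_brother",
                   "maternal_cousin", "paternal_cousin"]
        },
        "sex": {"enum": ["male", "female"]},
        "alive": {"type": "boolean"},
        "current_age": {"type": "number", "minimum": 0, "maximum": 120},
        "age_at_death": {"type": "number", "minimum": 0, "maximum": 120},
        "cause_of_death": {"type": "string"},
        "twin_status": {"enum": ["none", "identical", "fraternal"]},
        "history_known": {"type": "boolean"},
        "race_ethnicity": {"type": "string"},
        "ashkenazi": {"type": "boolean"},
        "consanguinity": {"type": "boolean"},
        "conditions": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["condition"],
            "properties": {
              "condition": {"type": "string"},
              "age_of_onset": {"type": "number", "minimum": 0, "maximum": 120},
              "label": {"type": "string"}
            }
          }
        }
      },
      "oneOf": [
        {"properties": {"alive": {"const": true}}, "required": ["current_age"]},
        {"properties": {"alive": {"const": false}}, "required": ["age_at_death"]},
        {"not": {"required": ["alive"]}}
      ]
    }
  }
}
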