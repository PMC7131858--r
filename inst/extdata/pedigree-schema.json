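{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "hboctriage/pedigree-schema/1.0",
  "title": "hboctriage pedigree",
  "description": "Canonical JSON form of a proband-rooted family history. The CSV dialect (one row per individual, diagnoses as repeated rows with the same id, empty cells for unknowns) is a flat projection of this schema.",
  "type": "object",
  "required": ["schema_version", "proband_id", "individuals"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "proband_id": {"type": "string", "minLength": 1},
    "individuals": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "sex", "diagnoses"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "sex": {"enum": ["female", "male"]},
          "age": {"type": "integer", "minimum": 0,
                  "description": "current age, or age at death; omit if unknown"},
          "alive": {"enum": ["yes", "no", "unknown"]},
          "mother_id": {"type": "string"},
          "father_id": {"type": "string"},
          "diagnoses": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["site"],
              "properties": {
                "site": {"enum": ["breast", "ovary"]},
                "age_at_onset": {"type": "integer", "minimum": 0,
                                 "description": "omit if unknown"},
                "laterality": {"enum": ["unilateral", "bilateral", "unknown"],
                               "description": "breast only; bilateral disease is one diagnosis"},
                "triple_negative": {"enum": ["yes", "no", "unknown"],
                                    "description": "breast only"},
                "mucinous": {"enum": ["yes", "no", "unknown"],
                             "description": "ovary only"},
                "borderline": {"enum": ["yes", "no", "unknown"],
                               "description": "ovary only"}
              }
            }
          }
        }
      }
    }
  }
}
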