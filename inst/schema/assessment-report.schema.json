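{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Stockpile assessment report",
  "type": "object",
  "required": ["municipality", "scenario", "victims", "rows"],
  "properties": {
    "municipality": {"type": "string"},
    "victims": {"type": "number", "minimum": 0},
    "scenario": {
      "type": "object",
      "required": ["affected_fraction", "days", "profile", "victim_rounding", "mark_boundary"],
      "properties": {
        "affected_fraction": {"type": "number", "minimum": 0, "maximum": 1},
        "days": {"type": "integer", "minimum": 1},
        "profile": {"type": "string"},
        "victim_rounding": {"enum": ["ceil", "round", "floor"]},
        "mark_boundary": {"enum": ["gte", "gt"]}
      }
    },
    "rows": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["nutrient", "name", "unit", "per_capita_daily", "required",
                     "supplied", "ratio_pct", "ratio_display", "mark",
                     "mark_label", "people_covered"],
        "properties": {
          "nutrient": {"type": "string"},
          "name": {"type": "string"},
          "unit": {"type": "string"},
          "per_capita_daily": {"type": "number", "minimum": 0},
          "required": {"type": "number", "minimum": 0},
          "supplied": {"type": "number", "minimum": 0},
          "ratio_pct": {"anyOf": [{"type": "number", "minimum": 0}, {"const": "Inf"}]},
          "ratio_display": {"type": "string"},
          "mark": {"enum": ["O", "x"]},
          "mark_label": {"enum": ["Ο", "×"]},
          "people_covered": {"type": "number", "minimum": 0}
        }
      }
    },
    "manifest": {"type": "object"}
  }
}
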