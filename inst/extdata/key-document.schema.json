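{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/coralkey/key-document.schema.json",
  "title": "coralkey key document",
  "description": "A polytomous identification key as a rooted decision graph of numbered couplets. Each lead either continues to another couplet ('next') or terminates at a taxon ('taxon'), never both.",
  "type": "object",
  "required": ["title", "source", "root", "couplets"],
  "additionalProperties": false,
  "properties": {
    "title": {"type": "string"},
    "source": {"type": "string"},
    "root": {"type": "integer", "minimum": 1},
    "metadata": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "generator": {"type": "string"},
        "seed": {"type": "integer"}
      }
    },
    "couplets": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "leads"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "integer", "minimum": 1},
          "group_label": {"type": "string"},
          "leads": {
            "type": "array",
            "minItems": 2,
            "maxItems": 26,
            "items": {
              "type": "object",
              "required": ["label", "statement"],
              "additionalProperties": false,
              "properties": {
                "label": {"type": "string", "pattern": "^[a-z]$"},
                "statement": {"type": "string", "minLength": 1},
                "group": {"type": "string"},
                "next": {"type": "integer", "minimum": 1},
                "taxon": {
                  "type": "object",
                  "required": ["genus", "regions"],
                  "additionalProperties": false,
                  "properties": {
                    "genus": {"type": "string", "pattern": "^[A-Z]"},
                    "subgenus": {"type": "string", "pattern": "^[A-Z]"},
                    "in_part": {"type": "boolean"},
                    "apozooxanthellate": {"type": "boolean"},
                    "regions": {"type": "array", "items": {"type": "string"}},
                    "figure": {"type": "string"}
                  }
                }
              },
              "oneOf": [{"required": ["next"]}, {"required": ["taxon"]}]
            }
          }
        }
      }
    }
  }
}
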