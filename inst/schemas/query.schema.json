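{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://medmod.example.org/schemas/query.schema.json",
  "title": "PQL query specification",
  "type": "object",
  "properties": {
    "conditions": {
      "type": "array",
      "description": "ordered filtering conditions",
      "items": {
        "oneOf": [
          {
            "type": "object",
            "required": ["type", "activity", "attribute", "op", "value"],
            "properties": {
              "type": {"const": "comparison"},
              "activity": {"type": "string"},
              "attribute": {"type": "string",
                "description": "attribute name, the reserved word 'count', or an interval name"},
              "op": {"enum": ["=", "!=", ">", "<", ">=", "<=", "contains", "begins_with", "ends_with"]},
              "value": {},
              "combine": {"enum": ["AND", "OR"]},
              "op2": {"enum": ["=", "!=", ">", "<", ">=", "<=", "contains", "begins_with", "ends_with"]},
              "value2": {}
            }
          },
          {
            "type": "object",
            "required": ["type", "activity", "function", "op", "value"],
            "properties": {
              "type": {"const": "aggregate"},
              "activity": {"type": "string"},
              "function": {"enum": ["Sum", "Average", "Count"]},
              "attribute": {"type": "string"},
              "op": {"enum": ["=", "!=", ">", "<", ">=", "<="]},
              "value": {"type": "number"}
            }
          }
        ]
      }
    },
    "partitions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["activity", "attribute", "direction", "k"],
        "properties": {
          "activity": {"type": "string"},
          "attribute": {"type": "string"},
          "direction": {"enum": ["Top", "Bottom"]},
          "k": {"type": "integer", "minimum": 1}
        }
      }
    },
    "intervals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "start_activity", "end_activity"],
        "properties": {
          "name": {"type": "string"},
          "start_activity": {"type": "string"},
          "start_attribute": {"type": "string"},
          "end_activity": {"type": "string"},
          "end_attribute": {"type": "string"},
          "pairing": {
            "type": "object",
            "required": ["start_attribute", "end_attribute"],
            "properties": {
              "start_attribute": {"type": "string"},
              "end_attribute": {"type": "string"}
            }
          }
        }
      }
    },
    "grouping": {
      "type": ["object", "null"],
      "required": ["activity", "attribute"],
      "properties": {
        "activity": {"type": "string"},
        "attribute": {"type": "string"}
      }
    },
    "retrievals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["type", "activity"],
        "properties": {
          "type": {"enum": ["count", "sum", "average", "table"]},
          "activity": {"type": "string"},
          "attribute": {"type": "string"}
        }
      }
    }
  }
}
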