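{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://medmod.example.org/schemas/trace.schema.json",
  "title": "MedMod runtime trace (slices of activity instances)",
  "type": "object",
  "required": ["slices"],
  "properties": {
    "model": {"type": "string"},
    "slices": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["slice_id", "instances"],
        "properties": {
          "slice_id": {"type": "string"},
          "instances": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["instance_id", "activity", "start_time"],
              "properties": {
                "instance_id": {"type": "string"},
                "activity": {"type": "string"},
                "start_time": {"type": "string", "format": "date-time"},
                "end_time": {"type": ["string", "null"], "format": "date-time"},
                "caused_by": {
                  "type": ["object", "null"],
                  "required": ["instance", "kind"],
                  "properties": {
                    "instance": {"type": "string"},
                    "kind": {"enum": ["follows", "composition", "interruption", "extension"]}
                  }
                },
                "attributes": {"type": "object",
                  "description": "attribute name -> typed value; absent values omitted"}
              }
            }
          }
        }
      }
    }
  }
}
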