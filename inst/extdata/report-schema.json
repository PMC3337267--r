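{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "alignqc check report",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["check_id", "status", "summary_counts", "findings"],
    "properties": {
      "check_id": {
        "enum": ["1", "2a", "2b", "3", "4", "5", "6", "7", "8", "9", "10"]
      },
      "status": {
        "enum": ["pass", "findings", "skipped", "not_applicable"]
      },
      "reason": { "type": "string" },
      "summary_counts": {
        "type": "object",
        "additionalProperties": { "type": ["number", "object", "null"] }
      },
      "findings": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["category", "entities", "evidence"],
          "properties": {
            "category": { "type": "string" },
            "entities": {
              "type": "array",
              "items": { "type": "string" }
            },
            "evidence": { "type": "string" }
          }
        }
      }
    }
  }
}
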