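{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "CDS-Hooks service response",
  "type": "object",
  "required": ["cards"],
  "properties": {
    "cards": {
      "type": "array",
      "items": { "$ref": "#/definitions/card" }
    }
  },
  "definitions": {
    "card": {
      "type": "object",
      "required": ["summary", "indicator", "source"],
      "properties": {
        "uuid": { "type": "string" },
        "summary": { "type": "string", "minLength": 1 },
        "detail": { "type": "string" },
        "indicator": { "type": "string", "enum": ["info", "warning", "critical"] },
        "source": {
          "type": "object",
          "required": ["label"],
          "properties": {
            "label": { "type": "string", "minLength": 1 },
            "url": { "type": "string" }
          }
        },
        "suggestions": {
          "type": "array",
          "minItems": 1,
          "items": { "$ref": "#/definitions/suggestion" }
        },
        "selectionBehavior": {
          "type": "string",
          "enum": ["at-most-one", "any"]
        }
      }
    },
    "suggestion": {
      "type": "object",
      "required": ["label", "actions"],
      "properties": {
        "label": { "type": "string", "minLength": 1 },
        "uuid": { "type": "string" },
        "actions": {
          "type": "array",
          "minItems": 1,
          "items": { "$ref": "#/definitions/action" }
        }
      }
    },
    "action": {
      "type": "object",
      "required": ["type", "description"],
      "properties": {
        "type": { "type": "string", "enum": ["create", "delete", "update"] },
        "description": { "type": "string" },
        "resource": { "type": "object" }
      }
    }
  }
}
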