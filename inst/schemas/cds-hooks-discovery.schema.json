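{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "CDS-Hooks discovery response",
  "type": "object",
  "required": ["services"],
  "properties": {
    "services": {
      "type": "array",
      "items": { "$ref": "#/definitions/service" }
    }
  },
  "definitions": {
    "service": {
      "type": "object",
      "required": ["id", "hook", "description"],
      "properties": {
        "id": { "type": "string", "minLength": 1 },
        "hook": { "type": "string", "minLength": 1 },
        "title": { "type": "string" },
        "description": { "type": "string", "minLength": 1 },
        "prefetch": { "type": "object" }
      }
    }
  }
}
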