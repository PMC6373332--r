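{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Coronary artery tree (labeled centerline forest)",
  "description": "Pathlines are ordered 3-D polylines in world millimetre coordinates. parent and attach_index are 0-based; attach_index points into the parent pathline's points array. Roots/fragments use null.",
  "type": "object",
  "required": ["format", "version", "ostia", "pathlines"],
  "properties": {
    "format": {"const": "coronary-tree"},
    "version": {"const": 1},
    "ostia": {
      "type": "object",
      "required": ["left", "right"],
      "properties": {
        "left":  {"$ref": "#/definitions/point"},
        "right": {"$ref": "#/definitions/point"}
      }
    },
    "pathlines": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["points"],
        "properties": {
          "label": {"type": ["string", "null"]},
          "parent": {"type": ["integer", "null"], "minimum": 0},
          "attach_index": {"type": ["integer", "null"], "minimum": 0},
          "points": {
            "type": "array",
            "minItems": 1,
            "items": {"$ref": "#/definitions/point"}
          }
        }
      }
    }
  },
  "definitions": {
    "point": {
      "type": "array",
      "minItems": 3,
      "maxItems": 3,
      "items": {"type": "number"}
    }
  }
}
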