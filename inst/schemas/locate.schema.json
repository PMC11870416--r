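{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "argspace ancestor location",
  "type": "object",
  "required": ["sample", "position", "time", "mean", "V", "bm_component",
               "root_component", "total_variance", "level", "region"],
  "properties": {
    "sample": {"type": "integer"},
    "position": {"type": "number"},
    "time": {"type": "number"},
    "mean": {"description": "length-d conditional mean"},
    "V": {"type": "number", "minimum": 0},
    "bm_component": {"type": "number", "minimum": 0},
    "root_component": {"type": "number", "minimum": 0},
    "total_variance": {"description": "d x d matrix"},
    "level": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "region": {"description": "interval (1D) or ellipse parameters (2D)"}
  }
}
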