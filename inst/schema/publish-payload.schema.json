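{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Tractometry publish payload",
  "description": "Dataset summary registered alongside a published tractometry bundle.",
  "type": "object",
  "required": ["schema_version", "n_subjects", "n_tracts", "n_nodes",
               "metric_names", "tract_names", "files"],
  "properties": {
    "schema_version": {"type": "string"},
    "n_subjects": {"type": "integer"},
    "n_tracts": {"type": "integer"},
    "n_nodes": {"type": "integer"},
    "metric_names": {"type": "array", "items": {"type": "string"}},
    "tract_names": {"type": "array", "items": {"type": "string"}},
    "metadata_columns": {"type": "array", "items": {"type": "string"}},
    "params": {"type": "object"},
    "files": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["path", "size", "sha256"],
        "properties": {
          "path": {"type": "string"},
          "size": {"type": "number"},
          "sha256": {"type": "string"}
        }
      }
    }
  }
}
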