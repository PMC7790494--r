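{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "ccntax/dendrogram.schema.json",
  "title": "Cell type taxonomy dendrogram",
  "description": "Nested tree of provisional cell types (leaves) and groups of types (internal nodes), optionally annotated with cell set tags.",
  "$ref": "#/$defs/node",
  "$defs": {
    "node": {
      "type": "object",
      "required": ["node_id"],
      "properties": {
        "node_id": {"type": "string", "minLength": 1},
        "original_label": {"type": "string"},
        "cell_set_accession": {"type": "string", "pattern": "^CS[0-9]{8}[0-9]+_[0-9]+$"},
        "cell_set_label": {"type": "string"},
        "cell_set_preferred_alias": {"type": "string"},
        "cell_set_aligned_alias": {"type": "string"},
        "children": {
          "type": "array",
          "items": {"$ref": "#/$defs/node"}
        }
      },
      "if": {
        "properties": {"children": {"maxItems": 0}}
      },
      "then": {
        "required": ["node_id", "original_label"]
      },
      "else": {
        "properties": {"children": {"minItems": 2}}
      },
      "additionalProperties": false
    }
  }
}
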