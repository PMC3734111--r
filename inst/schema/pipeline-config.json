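{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "atlasmine pipeline configuration",
  "type": "object",
  "required": ["out_dir", "atlas"],
  "properties": {
    "seed": { "type": "integer", "default": 1 },
    "out_dir": { "type": "string" },
    "atlas": {
      "type": "object",
      "required": ["source"],
      "properties": {
        "source": { "enum": ["simulate", "files"] },
        "sim": {
          "type": "object",
          "description": "overrides for sim_config(); see ?sim_config"
        },
        "signal": { "type": "string" },
        "meta": { "type": "string" },
        "calls": { "type": "string" }
      }
    },
    "analysis": {
      "type": "object",
      "properties": {
        "epithelial_tissues": { "type": "array", "items": { "type": "string" } },
        "reference_tissue": { "type": "string" },
        "tau": { "type": "number", "exclusiveMinimum": 0, "default": 2.5 },
        "top_n": { "type": "integer", "minimum": 1, "default": 50 },
        "floor": { "type": "number", "exclusiveMinimum": 0, "default": 1.0 }
      }
    },
    "gene_list": { "type": "string" },
    "specific_tissues": { "type": "array", "items": { "type": "string" } }
  }
}
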