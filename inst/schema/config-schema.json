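{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "omicspanel run configuration",
  "type": "object",
  "properties": {
    "study_dir": { "type": "string", "description": "directory written by write_study(); replaces metadata/datasets/response" },
    "metadata": { "type": "string", "description": "path to metadata CSV/TSV" },
    "datasets": {
      "type": "array", "minItems": 1,
      "items": {
        "type": "object",
        "properties": { "name": { "type": "string" }, "path": { "type": "string" } },
        "required": ["name", "path"]
      }
    },
    "response": {
      "type": "object",
      "properties": { "name": { "type": "string" }, "reference": { "type": "string" } },
      "required": ["name", "reference"]
    },
    "out_dir": { "type": "string" },
    "seed": { "type": "integer", "default": 1 },
    "figures": { "type": "boolean", "default": true },
    "pca": {
      "type": "object",
      "properties": {
        "k": { "type": "integer", "minimum": 1, "maximum": 5, "default": 2 },
        "scale": { "type": "boolean", "default": false },
        "fdr": { "type": "boolean", "default": true }
      }
    },
    "de": {
      "type": "object",
      "properties": {
        "method": { "enum": ["auto", "ols", "moderated", "voom"], "default": "auto" },
        "contrast": { "type": "array", "items": { "type": "string" }, "minItems": 2, "maxItems": 2 },
        "fdr": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1, "default": 0.05 }
      }
    },
    "enrich": {
      "type": "object",
      "properties": {
        "collections": {
          "type": "array",
          "items": {
            "type": "object",
            "properties": { "name": { "type": "string" }, "path": { "type": "string" } },
            "required": ["name", "path"]
          }
        },
        "pert_up": { "type": "string" },
        "pert_down": { "type": "string" },
        "fdr": { "type": "number", "default": 0.05 }
      }
    },
    "biomarker": {
      "type": "object",
      "properties": {
        "folds": { "type": "integer", "minimum": 2, "default": 5 },
        "repeats": { "type": "integer", "minimum": 1, "default": 5 },
        "alphas": { "type": "array", "items": { "type": "number", "minimum": 0, "maximum": 1 } },
        "n_lambda": { "type": "integer", "default": 20 },
        "metric": { "enum": ["auc", "accuracy"], "default": "auc" },
        "family": { "enum": ["gaussian_on_indicator", "binomial"], "default": "gaussian_on_indicator" },
        "level": { "type": "string" },
        "r_cutoff": { "type": "number", "default": 0.7 },
        "network_fdr": { "type": "number", "default": 0.05 }
      }
    },
    "metadata_stats": {
      "type": "object",
      "properties": { "mode": { "enum": ["regression", "nonparametric"], "default": "regression" } }
    },
    "simulate": {
      "type": "object",
      "description": "arguments forwarded to simulate_study(); presence enables the simulate stage in 'all'"
    },
    "report": {
      "type": "object",
      "properties": { "title": { "type": "string" } }
    }
  },
  "required": ["out_dir"]
}
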