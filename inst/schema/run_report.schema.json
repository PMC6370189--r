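{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "trmsig run report",
  "type": "object",
  "required": ["params", "counts", "pca", "clustering", "tier_table",
               "common_de", "comparisons_feeding_signature"],
  "properties": {
    "params": {
      "type": "object",
      "required": ["fpkm_cutoff", "alpha", "bootstraps", "n_perm",
                   "min_set_size", "q_cutoff", "seed", "stage_seeds"],
      "properties": {
        "fpkm_cutoff": {"type": "number", "minimum": 0},
        "alpha": {"type": "number", "exclusiveMinimum": 0},
        "bootstraps": {"type": "integer", "minimum": 1},
        "n_perm": {"type": "integer", "minimum": 1},
        "min_set_size": {"type": "integer", "minimum": 1},
        "q_cutoff": {"type": "number", "exclusiveMinimum": 0},
        "seed": {"type": "integer"},
        "stage_seeds": {"type": "object"}
      }
    },
    "counts": {
      "type": "object",
      "required": ["genes_input", "genes_expressed", "samples"]
    },
    "pca": {
      "type": "object",
      "required": ["variance_fraction", "top3_variance"]
    },
    "clustering": {
      "type": "object",
      "required": ["linkage", "distance", "two_cut_purity_tgfb"]
    },
    "tier_table": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["comparison", "tier", "total", "up", "down"]
      }
    },
    "common_de": {
      "type": "object",
      "required": ["n_up", "n_down", "n_total"]
    },
    "comparisons_feeding_signature": {"type": "array"},
    "overlap": {
      "type": ["object", "null"],
      "additionalProperties": {
        "type": "object",
        "required": ["o_obs", "k", "m", "N", "percent_overlap", "B", "p"]
      }
    },
    "gsea": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["set", "es", "nes", "p", "q", "significant"]
      }
    }
  }
}
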