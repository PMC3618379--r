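{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "nmrvalid validation report",
  "type": "object",
  "required": ["entry", "ensemble", "residues", "distance_constraints",
               "dihedral_constraints", "rdc", "shifts", "rog"],
  "properties": {
    "entry": {
      "type": "object",
      "required": ["name", "tool", "config"],
      "properties": {
        "name": {"type": "string"},
        "tool": {"type": "string"},
        "config": {"type": "object"}
      }
    },
    "ensemble": {
      "type": "object",
      "required": ["n_models", "n_residues", "representative_model",
                   "clusters"],
      "properties": {
        "n_models": {"type": "integer", "minimum": 1},
        "n_residues": {"type": "integer", "minimum": 1},
        "representative_model": {"type": "integer", "minimum": 1},
        "clusters": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["models", "representative"],
            "properties": {
              "models": {"type": "array", "items": {"type": "integer"}},
              "representative": {"type": "integer"}
            }
          }
        }
      }
    },
    "residues": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["chain", "resno", "resname", "s2", "rog",
                     "rationale"],
        "properties": {
          "chain": {"type": "string"},
          "resno": {"type": "integer"},
          "resname": {"type": "string"},
          "s2": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
          "n_long_range": {"type": "integer", "minimum": 0},
          "worst_distance_violation": {"type": ["number", "null"]},
          "worst_dihedral_violation": {"type": ["number", "null"]},
          "worst_abs_z": {"type": ["number", "null"]},
          "rog": {"enum": ["red", "orange", "green"]},
          "rationale": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "distance_constraints": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "range_class", "n_violated", "max_magnitude",
                     "mean_violating_magnitude"],
        "properties": {
          "id": {"type": "string"},
          "range_class": {"enum": ["intra", "short", "medium", "long"]},
          "n_violated": {"type": "integer", "minimum": 0},
          "max_magnitude": {"type": "number", "minimum": 0},
          "mean_violating_magnitude": {"type": "number", "minimum": 0}
        }
      }
    },
    "dihedral_constraints": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "chain", "resno", "angle", "n_violated",
                     "n_undefined", "max_magnitude",
                     "mean_violating_magnitude"]
      }
    },
    "rdc": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["medium", "convention", "n_constraints", "models",
                     "per_constraint", "mean_metrics"],
        "properties": {
          "convention": {"enum": ["raw", "prescaled"]},
          "models": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["model", "tensor", "rmsd_hz", "pearson_r",
                           "q_value", "condition_number", "degenerate"],
              "properties": {
                "tensor": {
                  "type": "object",
                  "required": ["matrix", "eigenvalues", "axes", "Da", "R"]
                }
              }
            }
          }
        }
      }
    },
    "shifts": {
      "type": "object",
      "required": ["offsets", "n_matched", "records"],
      "properties": {
        "offsets": {"type": "object"},
        "n_matched": {"type": "object"},
        "records": {"type": "array"}
      }
    },
    "rog": {
      "type": "object",
      "required": ["summary", "residues"],
      "properties": {
        "summary": {
          "type": "object",
          "required": ["n_red", "n_orange", "n_green"]
        },
        "residues": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["chain", "resno", "rog"]
          }
        }
      }
    }
  }
}
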