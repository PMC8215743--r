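{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "study_report",
  "type": "object",
  "required": ["header", "models", "information_criteria", "icc",
               "standardized", "cv_shrinkage", "dev_val", "endogeneity"],
  "properties": {
    "header": {
      "type": "object",
      "required": ["package", "version", "seed", "n_patients", "n_sites"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "seed": {"type": "integer"},
        "n_patients": {"type": "integer"},
        "n_sites": {"type": "integer"}
      }
    },
    "models": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "anyOf": [
          {"required": ["failed", "error"]},
          {"required": ["auc"]}
        ],
        "properties": {
          "auc": {"type": "number", "minimum": 0, "maximum": 1},
          "hl_stat": {"type": ["number", "null"]},
          "hl_p": {"type": ["number", "null"]},
          "belt_degree": {"type": ["integer", "null"]},
          "belt_p": {"type": ["number", "null"]},
          "citl": {"type": "number"},
          "slope": {"type": "number"},
          "eo_ratio": {"type": "number"},
          "binned_coverage": {"type": "number"},
          "aic": {"type": "number"},
          "bic": {"type": "number"},
          "n": {"type": "integer"},
          "failed": {"type": "boolean"},
          "error": {"type": "string"}
        }
      }
    },
    "information_criteria": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["model", "aic", "bic", "aic_rank", "bic_rank"]
      }
    },
    "icc": {
      "type": "object",
      "required": ["logit", "probit"],
      "additionalProperties": {
        "type": "object",
        "required": ["unconditional", "conditional", "r2_dichot"]
      }
    },
    "standardized": {"type": "object"},
    "loa": {
      "type": ["object", "null"],
      "required": ["mean_diff", "loa_lower", "loa_upper"]
    },
    "cv_shrinkage": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "anyOf": [
          {"required": ["failed", "error"]},
          {"required": ["shrink_in", "shrink_out", "overfit_pct"]}
        ]
      }
    },
    "dev_val": {"type": "object"},
    "endogeneity": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "anyOf": [
          {"required": ["failed", "error"]},
          {"required": ["rho_table", "ate", "atet", "margins", "converged"]}
        ]
      }
    },
    "truth": {"type": ["object", "null"]}
  }
}
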