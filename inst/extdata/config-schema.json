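{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "stepscea model configuration",
  "type": "object",
  "additionalProperties": false,
  "required": ["age_bands", "pa_prevalence", "rr_incidence", "rr_mortality",
               "utilities", "costs", "direct_indirect_ratio",
               "intervention_pa_shift", "control_pa_shift",
               "program_cost_annual", "compliance", "n_registered",
               "incidence_scale", "economics", "distributions"],
  "properties": {
    "age_bands": {
      "type": "array",
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["band", "age_lo", "age_hi", "fraction", "mortality",
                     "incidence_diabetes", "incidence_hypertension",
                     "complication_diabetes_cvd", "complication_hypertension_stroke",
                     "prev_healthy", "prev_diabetes", "prev_hypertension"],
        "properties": {
          "band": {"type": "string"},
          "age_lo": {"type": "number", "minimum": 17},
          "age_hi": {"type": "number"},
          "fraction": {"type": "number", "minimum": 0, "maximum": 1},
          "mortality": {"type": "number", "minimum": 0},
          "incidence_diabetes": {"type": "number", "minimum": 0},
          "incidence_hypertension": {"type": "number", "minimum": 0},
          "complication_diabetes_cvd": {"type": "number", "minimum": 0},
          "complication_hypertension_stroke": {"type": "number", "minimum": 0},
          "prev_healthy": {"type": "number", "minimum": 0, "maximum": 1},
          "prev_diabetes": {"type": "number", "minimum": 0, "maximum": 1},
          "prev_hypertension": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "pa_prevalence": {
      "type": "object",
      "description": "Row-stochastic 3-vectors (inactive, low, mod_high) per disease group",
      "required": ["healthy", "diabetes", "hypertension"]
    },
    "rr_incidence": {
      "type": "object",
      "description": "Onset relative risks per PA level; inactive entry is exactly 1",
      "required": ["diabetes", "hypertension", "diabetes_cvd", "hypertension_stroke"]
    },
    "rr_mortality": {
      "type": "object",
      "description": "Mortality relative risks for living groups plus scalar multipliers for the complication states",
      "required": ["healthy", "diabetes", "hypertension", "diabetes_cvd", "hypertension_stroke"]
    },
    "utilities": {
      "type": "object",
      "required": ["healthy", "diabetes", "hypertension", "diabetes_cvd",
                   "hypertension_stroke", "pa_delta"]
    },
    "costs": {
      "type": "object",
      "required": ["inpatient", "outpatient", "inpatient_proportion", "pa_multiplier"]
    },
    "direct_indirect_ratio": {
      "type": "object",
      "required": ["diabetes", "hypertension"]
    },
    "intervention_pa_shift": {"type": "array", "description": "3x3 row-stochastic matrix"},
    "control_pa_shift": {"type": "array", "description": "3x3 row-stochastic matrix"},
    "program_cost_annual": {"type": "number", "minimum": 0},
    "compliance": {"type": "number", "minimum": 0, "maximum": 1},
    "n_registered": {"type": "number", "exclusiveMinimum": 0},
    "incidence_scale": {"type": "number", "minimum": 0},
    "economics": {
      "type": "object",
      "additionalProperties": false,
      "required": ["discount_rate", "horizon_years", "cycle_length", "wtp_grid", "discount_timing"],
      "properties": {
        "discount_rate": {"type": "number", "minimum": 0},
        "horizon_years": {"type": "integer", "minimum": 1},
        "cycle_length": {"type": "number", "exclusiveMinimum": 0},
        "wtp_grid": {"type": "array", "items": {"type": "number"}},
        "discount_timing": {"enum": ["end", "mid"]}
      }
    },
    "distributions": {
      "type": "array",
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["name", "family", "p1", "range_rule"],
        "properties": {
          "name": {"type": "string"},
          "family": {"enum": ["beta", "gamma", "lognormal", "uniform", "degenerate"]},
          "p1": {"type": "number"},
          "p2": {"type": ["number", "null"]},
          "range_rule": {"enum": ["ci95", "iqr", "pm30"]}
        }
      }
    }
  }
}
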