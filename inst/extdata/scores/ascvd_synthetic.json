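{
  "_comment": "SYNTHETIC stand-in for a pooled-cohort atherosclerotic CVD equation: the required-input set and Cox functional form match that family of tools, but the coefficients are invented placeholders for pipeline and computability testing, not the published values.",
  "name": "ASCVD-form (synthetic coefficients)",
  "required_inputs": ["sex", "age", "total_cholesterol", "hdl_cholesterol", "systolic_bp", "bp_treated", "smoker", "diabetes"],
  "stratum_var": "sex",
  "transforms": {
    "age": "log",
    "total_cholesterol": "log",
    "hdl_cholesterol": "log",
    "systolic_bp": "log",
    "bp_treated": "identity",
    "smoker": "identity",
    "diabetes": "identity"
  },
  "coefficients": {
    "male": {
      "age": 2.5,
      "total_cholesterol": 0.8,
      "hdl_cholesterol": -0.9,
      "systolic_bp": 1.8,
      "bp_treated": 0.3,
      "smoker": 0.6,
      "diabetes": 0.6
    },
    "female": {
      "age": 2.8,
      "total_cholesterol": 0.9,
      "hdl_cholesterol": -1.0,
      "systolic_bp": 2.0,
      "bp_treated": 0.35,
      "smoker": 0.5,
      "diabetes": 0.7
    }
  },
  "lp_offset": {"male": 20.0, "female": 22.0},
  "baseline_survival": {"male": 0.91, "female": 0.96},
  "horizon_years": 10
}
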