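{
  "_comment": "SYNTHETIC stand-in for an INDANA-style calculator: includes a kidney-function input (serum creatinine) and height like that tool, but the coefficients are invented placeholders for pipeline and computability testing, not the published values.",
  "name": "INDANA-form (synthetic coefficients)",
  "required_inputs": ["age", "sex_male", "systolic_bp", "smoker", "diabetes", "serum_creatinine", "height"],
  "transforms": {
    "age": "identity",
    "sex_male": "identity",
    "systolic_bp": "identity",
    "smoker": "identity",
    "diabetes": "identity",
    "serum_creatinine": "log",
    "height": "identity"
  },
  "coefficients": {
    "age": 0.05,
    "sex_male": 0.4,
    "systolic_bp": 0.015,
    "smoker": 0.5,
    "diabetes": 0.55,
    "serum_creatinine": 0.3,
    "height": -0.01
  },
  "lp_offset": 4.1,
  "baseline_survival": 0.93,
  "horizon_years": 5
}
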