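{
  "_comment": "Sex-specific general cardiovascular disease risk function of the Framingham Heart Study (D'Agostino RB et al., Circulation 2008;117:743-53), 10-year horizon. The untreated-SBP coefficient is applied to all patients; lp_offset is the published cohort-mean linear predictor.",
  "name": "FHS general CVD",
  "required_inputs": ["sex", "age", "total_cholesterol", "hdl_cholesterol", "systolic_bp", "smoker", "diabetes"],
  "stratum_var": "sex",
  "transforms": {
    "age": "log",
    "total_cholesterol": "log",
    "hdl_cholesterol": "log",
    "systolic_bp": "log",
    "smoker": "identity",
    "diabetes": "identity"
  },
  "coefficients": {
    "male": {
      "age": 3.06117,
      "total_cholesterol": 1.1237,
      "hdl_cholesterol": -0.93263,
      "systolic_bp": 1.93303,
      "smoker": 0.65451,
      "diabetes": 0.57367
    },
    "female": {
      "age": 2.32888,
      "total_cholesterol": 1.20904,
      "hdl_cholesterol": -0.70833,
      "systolic_bp": 2.76157,
      "smoker": 0.52873,
      "diabetes": 0.69154
    }
  },
  "lp_offset": {"male": 23.9802, "female": 26.1931},
  "baseline_survival": {"male": 0.88936, "female": 0.95012},
  "horizon_years": 10
}
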