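{
  "_comment": "Synthetic marginal state prevalences P(X = s) for every non-reference state of the demonstration model. Values are plausible for a non-dialysis CKD outpatient population; they are not estimates from any cohort.",
  "age": {"<50": 0.12, "50-64": 0.28, "80+": 0.20},
  "gender": {"male": 0.55},
  "hdl_cholesterol": {"<40": 0.30, "60+": 0.25},
  "ldl_cholesterol": {"100-159": 0.45, "160+": 0.15},
  "bmi": {"25-29.9": 0.35, "30-34.9": 0.25, "35+": 0.12},
  "triglycerides": {"150-199": 0.25, "200+": 0.25},
  "diabetes": {"yes": 0.38},
  "hypertension": {"yes": 0.80},
  "smoking": {"former": 0.25, "current": 0.12},
  "cerebrovascular_disease": {"yes": 0.09},
  "coronary_artery_disease": {"yes": 0.19},
  "congestive_heart_failure": {"yes": 0.10},
  "peripheral_vascular_disease": {"yes": 0.09},
  "atrial_fibrillation": {"yes": 0.12},
  "glucose": {"100-125": 0.30, "126+": 0.30},
  "hstnt": {"14+": 0.35},
  "il6": {"5+": 0.30},
  "pth": {"65-299": 0.45, "300+": 0.15},
  "anemia": {"yes": 0.35},
  "alcohol": {"moderate": 0.40, "heavy": 0.10},
  "cancer": {"yes": 0.11},
  "copd": {"yes": 0.07},
  "connective_tissue_disorder": {"yes": 0.02},
  "liver_disease": {"yes": 0.04},
  "psychiatric_disease": {"yes": 0.01},
  "albumin": {"<3.5": 0.20},
  "proteinuria": {"A2": 0.30, "A3": 0.25},
  "crp": {"3-9.9": 0.35, "10+": 0.20},
  "egfr": {"G5": 0.05, "G4": 0.20, "G3b": 0.25, "G3a": 0.25, "G2": 0.15},
  "phosphate": {"4.5+": 0.15},
  "uric_acid": {"7+": 0.35}
}
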