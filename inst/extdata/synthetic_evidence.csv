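study_id,variable,exposure_state,measure,point,ci_low,ci_high,n,followup_years,pediatric,rrt,other_disease
syn-age-01,age,<50,OR,0.40,0.30,0.55,5000,5,FALSE,FALSE,FALSE
syn-age-02,age,50-64,OR,0.70,0.58,0.85,5000,5,FALSE,FALSE,FALSE
syn-age-03,age,80+,OR,1.60,1.30,1.95,4200,3,FALSE,FALSE,FALSE
syn-sex-01,gender,male,OR,1.30,1.10,1.55,6000,4,FALSE,FALSE,FALSE
syn-sex-02,gender,male,OR,1.55,1.20,2.00,4000,3,FALSE,FALSE,FALSE
syn-hdl-01,hdl_cholesterol,<40,OR,1.50,1.25,1.80,7000,6,FALSE,FALSE,FALSE
syn-hdl-02,hdl_cholesterol,60+,OR,0.80,0.66,0.97,7000,6,FALSE,FALSE,FALSE
syn-ldl-01,ldl_cholesterol,100-159,OR,1.20,1.02,1.42,6500,5,FALSE,FALSE,FALSE
syn-ldl-02,ldl_cholesterol,160+,OR,1.70,1.35,2.15,6500,5,FALSE,FALSE,FALSE
syn-bmi-01,bmi,25-29.9,OR,1.10,0.95,1.28,9000,4,FALSE,FALSE,FALSE
syn-bmi-02,bmi,30-34.9,OR,1.30,1.08,1.57,9000,4,FALSE,FALSE,FALSE
syn-bmi-03,bmi,35+,OR,1.60,1.25,2.05,9000,4,FALSE,FALSE,FALSE
syn-tg-01,triglycerides,150-199,OR,1.15,0.97,1.36,5200,5,FALSE,FALSE,FALSE
syn-tg-02,triglycerides,200+,OR,1.35,1.12,1.63,5200,5,FALSE,FALSE,FALSE
syn-dm-01,diabetes,yes,OR,1.90,1.65,2.19,12000,5,FALSE,FALSE,FALSE
syn-dm-02,diabetes,yes,OR,2.20,1.75,2.77,6000,3,FALSE,FALSE,FALSE
syn-dm-03,diabetes,yes,OR,2.50,1.60,3.90,1500,0.5,FALSE,FALSE,FALSE
syn-htn-01,hypertension,yes,OR,1.60,1.32,1.94,11000,6,FALSE,FALSE,FALSE
syn-smk-01,smoking,former,OR,1.25,1.05,1.49,8800,5,FALSE,FALSE,FALSE
syn-smk-02,smoking,current,OR,1.90,1.52,2.38,8800,5,FALSE,FALSE,FALSE
syn-cvd-01,cerebrovascular_disease,yes,OR,2.20,1.75,2.77,7600,4,FALSE,FALSE,FALSE
syn-cad-01,coronary_artery_disease,yes,OR,2.50,2.05,3.05,9800,5,FALSE,FALSE,FALSE
syn-chf-01,congestive_heart_failure,yes,HR,3.00,2.40,3.75,8200,4,FALSE,FALSE,FALSE
syn-pvd-01,peripheral_vascular_disease,yes,OR,2.00,1.58,2.53,6400,4,FALSE,FALSE,FALSE
syn-af-01,atrial_fibrillation,yes,OR,2.20,1.78,2.72,7100,5,FALSE,FALSE,FALSE
syn-glu-01,glucose,100-125,OR,1.15,0.98,1.35,8000,5,FALSE,FALSE,FALSE
syn-glu-02,glucose,126+,OR,1.40,1.16,1.69,8000,5,FALSE,FALSE,FALSE
syn-tnt-01,hstnt,14+,HR,2.60,2.05,3.30,4300,3,FALSE,FALSE,FALSE
syn-il6-01,il6,5+,OR,1.90,1.48,2.44,3900,3,FALSE,FALSE,FALSE
syn-pth-01,pth,65-299,OR,1.10,0.92,1.32,5600,4,FALSE,FALSE,FALSE
syn-pth-02,pth,300+,OR,1.50,1.18,1.91,5600,4,FALSE,FALSE,FALSE
syn-ane-01,anemia,yes,OR,1.70,1.42,2.04,10400,5,FALSE,FALSE,FALSE
syn-ane-02,anemia,yes,OR,1.95,1.30,2.93,2100,4,FALSE,TRUE,FALSE
syn-alc-01,alcohol,moderate,OR,0.90,0.76,1.07,7300,6,FALSE,FALSE,FALSE
syn-alc-02,alcohol,heavy,OR,1.40,1.09,1.80,7300,6,FALSE,FALSE,FALSE
syn-can-01,cancer,yes,OR,1.40,1.13,1.74,8900,4,FALSE,FALSE,FALSE
syn-copd-01,copd,yes,OR,1.80,1.41,2.30,7700,4,FALSE,FALSE,FALSE
syn-ctd-01,connective_tissue_disorder,yes,OR,1.50,1.02,2.21,4100,5,FALSE,FALSE,FALSE
syn-liv-01,liver_disease,yes,OR,1.50,1.08,2.09,5200,4,FALSE,FALSE,FALSE
syn-psy-01,psychiatric_disease,yes,OR,1.30,0.87,1.95,4800,4,FALSE,FALSE,FALSE
syn-alb-01,albumin,<3.5,OR,1.90,1.55,2.33,9100,4,FALSE,FALSE,FALSE
syn-upr-01,proteinuria,A2,RR,1.30,1.08,1.57,10200,5,FALSE,FALSE,FALSE
syn-upr-02,proteinuria,A3,RR,2.10,1.72,2.57,10200,5,FALSE,FALSE,FALSE
syn-crp-01,crp,3-9.9,OR,1.40,1.17,1.68,6800,4,FALSE,FALSE,FALSE
syn-crp-02,crp,10+,OR,2.20,1.76,2.75,6800,4,FALSE,FALSE,FALSE
syn-gfr-01,egfr,G2,OR,1.10,0.91,1.33,11500,5,FALSE,FALSE,FALSE
syn-gfr-02,egfr,G3a,OR,1.40,1.17,1.68,11500,5,FALSE,FALSE,FALSE
syn-gfr-03,egfr,G3b,OR,1.80,1.48,2.19,11500,5,FALSE,FALSE,FALSE
syn-gfr-04,egfr,G4,OR,2.30,1.86,2.84,9000,5,FALSE,FALSE,FALSE
syn-gfr-05,egfr,G4,OR,2.60,1.95,3.47,3000,3,FALSE,FALSE,FALSE
syn-gfr-06,egfr,G4,OR,2.80,1.70,4.61,900,8,TRUE,FALSE,FALSE
syn-gfr-07,egfr,G5,OR,3.20,2.45,4.18,6200,4,FALSE,FALSE,FALSE
syn-pho-01,phosphate,4.5+,OR,1.50,1.22,1.84,8600,5,FALSE,FALSE,FALSE
syn-ua-01,uric_acid,7+,OR,1.30,1.09,1.55,9300,5,FALSE,FALSE,FALSE
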