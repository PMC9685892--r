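order,antecedent,coverage_pct,confidence_pct,or,aor,aor_ci_low,aor_ci_high
1,pdx_Cardiac.Arrest,1.6,59.3,11.89,13.09,9.21,18.57
1,dx_Encounter.for.counseling,0.7,64.7,14.39,13.01,7.75,21.83
1,ddx_DNR,0.4,65.9,14.97,12.12,6.35,23.14
1,pl_Acute.respiratory.failure,9.6,29.4,3.83,4.00,3.37,4.73
1,dx_Other.ascites,1.1,28.0,2.98,3.56,2.26,5.60
1,ddx_Acute.respiratory.failure,1.2,33.3,3.87,3.39,2.23,5.14
1,cm_Acidosis,12.6,25.0,3.07,3.37,2.87,3.95
1,dx_Hypothermia.due.to.exposure,0.5,30.4,3.33,3.26,1.69,6.26
1,hx_ARF.with.tubular.necrosis,0.9,24.4,2.46,2.65,1.57,4.45
1,hx_Coagulopathy,1.3,29.1,3.16,2.54,1.68,3.84
2,pl_Atelectasis & dx_Encounter.for.counseling,0.3,76.7,25.32,24.75,10.29,59.50
2,cm_Acidosis & pdx_Cardiac.Arrest,0.5,72.6,20.63,21.97,11.62,41.52
2,pl_Hypotension & pdx_Cardiac.Arrest,0.2,68.0,16.27,20.12,8.53,47.47
2,cm_Essential.Hypertension & ddx_DNR,0.3,74.2,22.15,18.22,7.95,41.72
2,cm_Essential.Hypertension & dx_Encounter.for.counseling,0.4,72.5,20.42,16.37,8.02,33.36
2,pl_Acute.respiratory.failure & pdx_Cerebral.Hemorrhage,0.5,55.1,9.47,8.37,4.68,14.96
2,cm_Congestive.heart.failure & hx_ARF.with.tubular.necrosis,0.3,50.0,7.63,6.72,3.14,14.35
2,pl_Atelectasis & ddx_Acute.respiratory.failure,0.3,42.3,5.57,5.71,2.54,12.79
2,pl_Acute.respiratory.failure & dx_Encounter.due.to.CABG,0.4,44.4,6.11,5.55,2.82,10.91
2,ddx_Kidney.Failure.Acute & ddx_Atrial.Fibrillation,0.2,48.0,7.03,5.55,2.47,12.43
3,pl_Dyspnea & pl_Hypotension & pl_Acute.respiratory.failure,0.3,48.0,7.03,7.90,3.49,17.88
3,cm_Acidosis & pl_Atrial.Fibrillation & pl_Hypotension,0.4,50.0,7.65,6.91,3.46,13.76
3,cm_Essential.Hypertension & pl_Hypotension & dx_ECG.abnormalities.non.specific,0.3,42.9,5.71,6.32,2.93,13.60
3,cm_Anemia & cm_Acidosis & dx_Long.term.use.of..medications,0.4,46.0,6.50,6.00,3.07,11.70
3,pl_Kidney.Failure.Acute & cm_Acidosis & cm_Chronic.atrial.fibrillation,0.6,48.2,7.07,5.94,2.72,12.95
3,cm_Congestive.heart.failure & cm_Acidosis & dx_Long.term.use.of..medications,0.6,43.2,5.82,5.92,2.98,11.73
3,cm_Congestive.heart.failure & pl_Acute.respiratory.failure & dx_abnormal.blood.chemistry,0.3,46.4,6.60,5.58,2.57,12.10
3,cm_Essential.Hypertension & pl_Acute.respiratory.failure & cm_Chronic.Kidney.Diseases,0.4,45.7,6.43,5.57,2.81,11.00
3,cm_Anemia & cm_Acidosis & pl_Acute.respiratory.failure,0.7,40.0,5.13,5.32,3.19,8.87
3,cm_Essential.Hypertension & pl_Hypotension & pl_Acute.respiratory.failure,0.6,41.1,5.35,5.26,3.03,9.13
4,cm_Essential.Hypertension & cm_Anemia & cm_Acidosis & pl_Acute.respiratory.failure,0.2,52.0,8.26,8.76,3.96,19.40
4,pl_Kidney.Failure.Acute & cm_Anemia & cm_Acidosis & pl_Acute.respiratory.failure,0.3,50.0,7.63,7.75,3.65,16.47
4,pl_Kidney.Failure.Acute & cm_Acidosis & pl_Acute.respiratory.failure & cm_Chronic.Kidney.Diseases,0.3,48.3,7.12,7.53,3.56,15.91
4,cm_Essential.Hypertension & dx_Abmoral.EKG & pl_Hypotension & dx_ECG.abnormalities.non.specific,0.2,46.2,6.53,7.02,3.19,15.48
4,pl_Kidney.Failure.Acute & cm_Congestive.heart.failure & cm_Acidosis & cm_Chronic.Kidney.Diseases,0.3,46.4,6.61,6.49,3.02,13.95
4,pl_Dyspnea & pl_Kidney.Failure.Acute & cm_Acidosis & cm_Chronic.kidney.disease.stage.3.moderate,0.3,46.4,6.61,5.43,2.54,11.61
4,pl_Dyspnea & pl_Kidney.Failure.Acute & cm_Acidosis & cm_Chronic.Kidney.Diseases,0.3,39.3,4.92,5.28,2.40,11.61
4,pl_Kidney.Failure.Acute & cm_Acidosis & pl_Atrial.Fibrillation & pl_Acute.respiratory.failure,0.2,40.0,5.07,5.20,2.29,11.80
4,cm_Essential.Hypertension & dx_Abmoral.EKG & cm_Acidosis & pl_Hypotension,0.3,35.5,5.21,5.19,2.51,10.74
4,cm_Essential.Hypertension & dx_Encounter.due.to.tobacco & pl_Atrial.Fibrillation & pl_Acute.respiratory.failure,0.4,39.3,6.56,4.92,2.59,9.38
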