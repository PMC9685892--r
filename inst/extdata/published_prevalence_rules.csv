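order,antecedent,lift,confidence_pct
2,pl_Atelectasis & dx_Encounter.for.counseling,6.54,76.7
2,cm_Essential.Hypertension & ddx_DNR,6.33,74.2
2,cm_Acidosis & pdx_Cardiac.Arrest,6.20,72.6
2,cm_Essential.Hypertension & dx_Encounter.for.counseling,6.19,68.0
2,pl_Hypotension & pdx_Cardiac.Arrest,5.80,65.9
2,pl_Acute.respiratory.failure & pdx_Cerebral.Hemorrhage,4.70,55.1
2,cm_Congestive.heart.failure & hx_ARF.with.tubular.necrosis,4.27,50.0
2,cm_Altered.mental.status & hx_Atherosclerosis.without.angina,4.10,48.0
2,ddx_Kidney.Failure.Acute & ddx_Atrial.Fibrillation,4.10,48.0
2,ddx_Coronary.atherosclerosis.of.native & ddx_Acute.respiratory.failure,4.03,47.2
3,cm_Essential.Hypertension & dx_Abmoral.EKG & dx_Encounter.for.counseling,6.57,77.0
3,cm_Acidosis & pl_Atrial.Fibrillation & pl_Hypotension,4.27,50.0
3,pl_Dyspnea & pl_Hypotension & pl_Acute.respiratory.failure,4.10,48.0
3,cm_Congestive.heart.failure & dx_Abmoral.EKG & pl_Atrial.Fibrillation,4.13,48.4
3,pl_Kidney.Failure.Acute & cm_Acidosis & cm_Chronic.atrial.fibrillation,4.11,48.2
3,cm_Congestive.heart.failure & pl_Acute.respiratory.failure & dx_abnormal.blood.chemistry,3.96,46.4
3,cm_Anemia & cm_Acidosis & dx_Long.term.use.of..medications,3.92,46.0
3,cm_Essential.Hypertension & pl_Acute.respiratory.failure & cm_Chronic.Kidney.Diseases,3.90,45.7
3,cm_Congestive.heart.failure & pl_Atrial.Fibrillation & cm_Altered.mental.status,3.79,44.4
3,cm_Essential.Hypertension & pl_Acute.respiratory.failure & cm_Altered.mental.status,3.75,43.9
4,cm_Essential.Hypertension & cm_Anemia & cm_Acidosis & pl_Acute.respiratory.failure,4.44,52.0
4,pl_Kidney.Failure.Acute & cm_Anemia & cm_Acidosis & pl_Acute.respiratory.failure,4.27,50.0
4,pl_Kidney.Failure.Acute & cm_Acidosis & pl_Acute.respiratory.failure & cm_Chronic.Kidney.Diseases,4.12,48.3
4,pl_Dyspnea & pl_Kidney.Failure.Acute & cm_Acidosis & cm_Chronic.kidney.disease.stage.3.moderate,3.96,46.4
4,pl_Kidney.Failure.Acute & cm_Congestive.heart.failure & cm_Acidosis & cm_Chronic.Kidney.Diseases,3.96,46.4
4,cm_Essential.Hypertension & dx_Encounter.due.to.tobacco & pl_Acute.respiratory.failure & ddx_Coronary.atherosclerosis.of.native,3.94,46.2
4,cm_Essential.Hypertension & dx_Abmoral.EKG & pl_Hypotension & dx_ECG.abnormalities.non.specific,3.94,46.2
4,cm_Essential.Hypertension & dx_Encounter.due.to.tobacco & pl_Acute.respiratory.failure & hx_Coronary.atherosclerosis.of.native,3.79,44.4
4,pl_Kidney.Failure.Acute & cm_Congestive.heart.failure & pl_Acute.respiratory.failure & cm_Chronic.kidney.disease.stage.3.moderate,3.70,43.3
4,cm_Essential.Hypertension & dx_Abmoral.EKG & cm_Acidosis & pl_Hypotension,3.47,40.6
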