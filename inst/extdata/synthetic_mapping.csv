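# Synthetic code mapping for the packaged default cohort configuration.
# Codes are invented ICD-10-style placeholders (NOT real ICD-10-CM codes);
# one distinct code per catalog item so the record round trip is exact.
"code","code_system","concept","subcategory","precedence"
"P01.2","icd10","Cardiac.Arrest","pdx",1
"P02.3","icd10","Cerebral.Hemorrhage","pdx",1
"P03.4","icd10","Sepsis","pdx",1
"P04.5","icd10","Acute.Myocardial.Infarction","pdx",1
"P05.6","icd10","Pneumonia","pdx",1
"P06.7","icd10","GI.Bleed","pdx",1
"P07.8","icd10","Ischemic.Stroke","pdx",1
"L01.2","icd10","Acute.respiratory.failure","pl",1
"L02.3","icd10","Hypotension","pl",1
"L03.4","icd10","Atelectasis","pl",1
"L04.5","icd10","Atrial.Fibrillation","pl",1
"L05.6","icd10","Dyspnea","pl",1
"L06.7","icd10","Kidney.Failure.Acute","pl",1
"L07.8","icd10","Pleural.Effusion","pl",1
"L08.9","icd10","Hyperglycemia","pl",1
"L09.1","icd10","Electrolyte.Imbalance","pl",1
"L10.2","icd10","Peripheral.Edema","pl",1
"L11.3","icd10","Tachycardia","pl",1
"L12.4","icd10","Nausea.and.Vomiting","pl",1
"D01.2","icd10","Encounter.for.counseling","dx",1
"D02.3","icd10","Abmoral.EKG","dx",1
"D03.4","icd10","abnormal.blood.chemistry","dx",1
"D04.5","icd10","Long.term.use.of..medications","dx",1
"D05.6","icd10","ECG.abnormalities.non.specific","dx",1
"D06.7","icd10","Encounter.due.to.tobacco","dx",1
"D07.8","icd10","Other.ascites","dx",1
"D08.9","icd10","Hypothermia.due.to.exposure","dx",1
"D09.1","icd10","Encounter.due.to.CABG","dx",1
"D10.2","icd10","Chest.Pain","dx",1
"D11.3","icd10","Fever","dx",1
"D12.4","icd10","Abdominal.Pain","dx",1
"D13.5","icd10","Fatigue","dx",1
"D14.6","icd10","Dehydration","dx",1
"D15.7","icd10","Cough","dx",1
"D16.8","icd10","Back.Pain","dx",1
"D17.9","icd10","Dizziness","dx",1
"D18.1","icd10","Headache","dx",1
"D19.2","icd10","Weakness","dx",1
"C01.2","icd10","Essential.Hypertension","cm",1
"C02.3","icd10","Acidosis","cm",1
"C03.4","icd10","Congestive.heart.failure","cm",1
"C04.5","icd10","Anemia","cm",1
"C05.6","icd10","Chronic.Kidney.Diseases","cm",1
"C06.7","icd10","Altered.mental.status","cm",1
"C07.8","icd10","Chronic.atrial.fibrillation","cm",1
"C08.9","icd10","Chronic.kidney.disease.stage.3.moderate","cm",1
"C09.1","icd10","Diabetes.Mellitus","cm",1
"C10.2","icd10","Hyperlipidemia","cm",1
"C11.3","icd10","COPD","cm",1
"C12.4","icd10","Obesity","cm",1
"C13.5","icd10","Hypothyroidism","cm",1
"C14.6","icd10","Coronary.Artery.Disease","cm",1
"C15.7","icd10","GERD","cm",1
"C16.8","icd10","Tobacco.Use","cm",1
"H01.2","icd10","ARF.with.tubular.necrosis","hx",1
"H02.3","icd10","Coagulopathy","hx",1
"H03.4","icd10","Atherosclerosis.without.angina","hx",1
"H04.5","icd10","Coronary.atherosclerosis.of.native","hx",1
"H05.6","icd10","Prior.Myocardial.Infarction","hx",1
"H06.7","icd10","Prior.Stroke","hx",1
"H07.8","icd10","Malignancy.History","hx",1
"H08.9","icd10","Prior.Major.Surgery","hx",1
"X01.2","icd10","DNR","ddx",1
"X02.3","icd10","Acute.respiratory.failure","ddx",1
"X03.4","icd10","Kidney.Failure.Acute","ddx",1
"X04.5","icd10","Atrial.Fibrillation","ddx",1
"X05.6","icd10","Coronary.atherosclerosis.of.native","ddx",1
"X06.7","icd10","Anemia","ddx",1
"X07.8","icd10","Heart.Failure","ddx",1
"X08.9","icd10","Sepsis.Resolved","ddx",1
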