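# Guideline consultation checklist for an undiagnosed type 2 diabetes case:
# 19 recommended history questions and 13 recommended examinations, with the
# essential subset flagged. Item wording is a representative rendering of the
# national clinical guideline standard for first-visit T2D assessment.
denominator_mode: component_sum
fixed_total: 31
items:
  - {id: q_dry_mouth_thirst,      kind: question,    essential: true,  label: "Dry mouth or excessive thirst (polydipsia)"}
  - {id: q_polyuria,              kind: question,    essential: true,  label: "Frequent or increased urination (polyuria)"}
  - {id: q_polyphagia,            kind: question,    essential: false, label: "Increased appetite / eating more (polyphagia)"}
  - {id: q_weight_change,         kind: question,    essential: true,  label: "Recent unexplained weight change"}
  - {id: q_family_history,        kind: question,    essential: true,  label: "Family history of diabetes"}
  - {id: q_prior_glucose_test,    kind: question,    essential: true,  label: "Previous blood glucose testing"}
  - {id: q_diabetes_history,      kind: question,    essential: true,  label: "Personal history of diabetes diagnosis"}
  - {id: q_age,                   kind: question,    essential: false, label: "Patient age"}
  - {id: q_symptom_duration,      kind: question,    essential: false, label: "Duration of current symptoms"}
  - {id: q_fatigue,               kind: question,    essential: false, label: "Fatigue or weakness"}
  - {id: q_blurred_vision,        kind: question,    essential: false, label: "Blurred vision"}
  - {id: q_numbness,              kind: question,    essential: false, label: "Numbness or tingling in extremities"}
  - {id: q_skin_healing,          kind: question,    essential: false, label: "Skin infections or slow wound healing"}
  - {id: q_nocturia,              kind: question,    essential: false, label: "Night-time urination (nocturia)"}
  - {id: q_current_medication,    kind: question,    essential: false, label: "Current medication use"}
  - {id: q_hypertension_history,  kind: question,    essential: false, label: "History of hypertension"}
  - {id: q_smoking,               kind: question,    essential: false, label: "Smoking habits"}
  - {id: q_alcohol,               kind: question,    essential: false, label: "Alcohol consumption"}
  - {id: q_diet,                  kind: question,    essential: false, label: "Dietary habits"}
  - {id: e_capillary_glucose,     kind: examination, essential: false, label: "Capillary (postprandial) blood glucose test"}
  - {id: e_fpg,                   kind: examination, essential: true,  label: "Fasting plasma glucose (FPG)"}
  - {id: e_hba1c,                 kind: examination, essential: true,  label: "Glycated haemoglobin (HbA1c)"}
  - {id: e_ogtt,                  kind: examination, essential: true,  label: "Oral glucose tolerance test (OGTT)"}
  - {id: e_bmi,                   kind: examination, essential: true,  label: "Body-mass index (BMI)"}
  - {id: e_height,                kind: examination, essential: false, label: "Height measurement"}
  - {id: e_weight,                kind: examination, essential: false, label: "Weight measurement"}
  - {id: e_blood_pressure,        kind: examination, essential: false, label: "Blood pressure measurement"}
  - {id: e_urine,                 kind: examination, essential: false, label: "Urine glucose / ketone test"}
  - {id: e_lipids,                kind: examination, essential: false, label: "Blood lipid panel"}
  - {id: e_renal,                 kind: examination, essential: false, label: "Renal function test"}
  - {id: e_foot,                  kind: examination, essential: false, label: "Foot examination"}
  - {id: e_fundus,                kind: examination, essential: false, label: "Visual acuity / fundus examination"}
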