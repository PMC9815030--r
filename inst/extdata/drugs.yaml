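# Drug classification for the standardized T2D case.
#   correct: guideline first/second-line glucose-lowering therapy
#   neutral: neither indicated nor contraindicated for the case
#   harmful: contraindicated or glucose-raising for an undiagnosed T2D patient
# Names are matched after case-folding and whitespace stripping; a dispensed
# drug absent from this list is an error, never a silent default.
correct:
  - metformin
  - glipizide
  - gliclazide
  - glibenclamide
  - glimepiride
  - acarbose
  - sitagliptin
  - pioglitazone
  - repaglinide
  - insulin
neutral:
  - vitamin_b
  - vitamin_c
  - amoxicillin
  - ibuprofen
  - paracetamol
  - omeprazole
  - herbal_tonic
  - calcium_tablet
harmful:
  - dexamethasone
  - prednisone
  - hydrocortisone
  - glucose_injection
  - unlabeled_hypoglycemic_mix
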