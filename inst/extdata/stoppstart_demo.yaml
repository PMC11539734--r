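# Demo rule base.
#
# Rules D2 and D6 are the two published formalization examples from the
# STOPP/START v2 guideline:
#   START D2: "Start fibre supplements (e.g. bran, ispaghula, methylcellulose,
#              sterculia) for diverticulosis with a history of constipation"
#   STOPP D6: "Stop antipsychotics (i.e. other than quetiapine or clozapine)
#              in those with parkinsonism or Lewy Body Disease"
# Rules X1-X8 are NON-NORMATIVE illustrative rules authored for this package
# to exercise every display-rule generator; they are NOT taken from the
# guideline and must not be used for clinical decisions.
conditions:
  - {id: constipation, kind: clinical, label: History of constipation,
     category: digestive system, codes: [ICD10:K59.0], default_code: 1}
  - {id: diverticulosis, kind: clinical, label: Diverticulosis,
     category: digestive system, codes: [ICD10:K57.9, ICD10:K57.3], default_code: 1}
  - {id: parkinsonism, kind: clinical, label: Parkinsonism,
     category: neurology, codes: [ICD10:G20, ICD10:G21], default_code: 1}
  - {id: lewy_body, kind: clinical, label: Lewy Body disease,
     category: neurology, codes: [ICD10:G31.8], default_code: 1}
  - {id: ankle_edema, kind: clinical, label: Ankle edema,
     category: cardiology, codes: [ICD10:R60.0], default_code: 1}
  - {id: heart_failure, kind: clinical, label: Heart failure,
     category: cardiology, codes: [ICD10:I50, ICD10:I50.9], default_code: 1}
  - {id: diabetes, kind: clinical, label: Diabetes mellitus,
     category: endocrinology and metabolism,
     codes: [ICD10:E14, ICD10:E10, ICD10:E11], default_code: 1}
  - {id: proteinuria, kind: clinical, label: Proteinuria,
     category: urogenital, codes: [ICD10:R80], default_code: 1}
  - {id: falls, kind: clinical, label: Recurrent falls,
     category: general and other, codes: [ICD10:R29.6], default_code: 1}
  - {id: dementia, kind: clinical, label: Dementia,
     category: psychiatry, codes: [ICD10:F03], default_code: 1}
  - {id: stroke, kind: clinical, label: History of stroke,
     category: neurology, codes: [ICD10:I64], default_code: 1}
  - {id: hypertension, kind: clinical, label: Hypertension,
     category: cardiology, codes: [ICD10:I10], default_code: 1}
  - {id: glaucoma, kind: clinical, label: Glaucoma,
     category: ophthalmology and ENT, codes: [ICD10:H40], default_code: 1}
  - {id: fibre, kind: nonclinical, label: Fibre supplements,
     category: general and other, codes: [ATC:A06AC], default_code: 1}
  - {id: antipsychotic, kind: nonclinical, label: Antipsychotic,
     category: general and other, codes: [ATC:N05A], default_code: 1}
  - {id: opioid, kind: nonclinical, label: Opioid,
     category: general and other, codes: [ATC:N02A], default_code: 1}
  - {id: laxative, kind: nonclinical, label: Laxative,
     category: general and other, codes: [ATC:A06A], default_code: 1}
  - {id: nsaid, kind: nonclinical, label: NSAID,
     category: general and other, codes: [ATC:M01A], default_code: 1}
  - {id: betablocker, kind: nonclinical, label: Beta-blocker,
     category: general and other, codes: [ATC:C07A], default_code: 1}
  - {id: loop_diuretic, kind: nonclinical, label: Loop diuretic,
     category: general and other, codes: [ATC:C03C], default_code: 1}
  - {id: low_egfr, kind: nonclinical, label: "eGFR < 60 ml/min (lab)",
     category: urogenital, codes: ["LOINC:62238-1"], default_code: 1}
rules:
  - id: D2
    present_clinical: [constipation, diverticulosis]
    absent_nonclinical: [fibre]
    action: start(fibre)
  - id: D6
    present_nonclinical: [antipsychotic]
    unions:
      - clinical: [parkinsonism, lewy_body]
    action: stop(antipsychotic)
  # ---- illustrative, non-normative rules below this line ----
  - id: X1  # drug-only premise: generates no display rules
    present_nonclinical: [opioid]
    absent_nonclinical: [laxative]
    action: start(laxative)
  - id: X2  # present + absent clinical conditions
    present_clinical: [ankle_edema]
    absent_clinical: [heart_failure]
    action: review(diuretic)
  - id: X3  # mixed clinical/lab union
    present_clinical: [diabetes]
    unions:
      - clinical: [proteinuria]
        nonclinical: [low_egfr]
    action: start(ace_inhibitor)
  - id: X4  # drug-gated absent clinical condition
    present_nonclinical: [nsaid]
    absent_clinical: [stroke]
    action: review(nsaid)
  - id: X5  # two unions in one rule
    present_nonclinical: [betablocker]
    unions:
      - clinical: [falls]
      - clinical: [dementia]
        nonclinical: [antipsychotic]
    action: review(betablocker)
  - id: X6  # two present clinical conditions, absent drug
    present_clinical: [hypertension, heart_failure]
    absent_nonclinical: [betablocker]
    action: start(betablocker)
  - id: X7  # singleton clinical union
    present_nonclinical: [loop_diuretic]
    unions:
      - clinical: [glaucoma]
    action: review(loop_diuretic)
  - id: X8  # pure clinical conjunction (no drug gate)
    present_clinical: [dementia, stroke]
    action: review(anticholinergic_burden)
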