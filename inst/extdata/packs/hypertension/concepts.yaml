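# Clinical concepts for the hypertension section. Concepts printed in the
# specification tables carry their published codings; concepts needed by
# the rules but not printed code-for-code are marked inferred.
concepts:
  - id: SBP
    label: Systolic blood pressure
    kind: vital-sign
    resource_type: Observation
    codings:
      - {system: LOINC, code: "8480-6", display: Systolic blood pressure}
    unit: "mm[Hg]"
    value_type: quantity
    sources: [EHR, HHMP]
  - id: DBP
    label: Diastolic blood pressure
    kind: vital-sign
    resource_type: Observation
    codings:
      - {system: LOINC, code: "8482-4", display: Diastolic blood pressure}
    unit: "mm[Hg]"
    value_type: quantity
    sources: [EHR, HHMP]
  - id: HeartRate
    label: Heart rate
    kind: vital-sign
    resource_type: Observation
    codings:
      - {system: LOINC, code: "8867-4", display: Heart rate}
    unit: "/min"
    value_type: quantity
    sources: [EHR, HHMP]
    inferred: true
  - id: SerumPotassium
    label: Serum potassium
    kind: lab-result
    resource_type: Observation
    codings:
      - {system: LOINC, code: "2823-3", display: "Potassium [Moles/volume] in Serum or Plasma"}
    unit: mmol/L
    value_type: quantity
    sources: [EHR]
    inferred: true
  - id: eGFR
    label: Estimated glomerular filtration rate
    kind: lab-result
    resource_type: Observation
    codings:
      - {system: LOINC, code: "33914-3", display: "Glomerular filtration rate (estimated)"}
    unit: mL/min
    value_type: quantity
    sources: [EHR]
    inferred: true
  - id: LVEF
    label: Left ventricular ejection fraction
    kind: lab-result
    resource_type: Observation
    codings:
      - {system: LOINC, code: "10230-1", display: Left ventricular ejection fraction}
    unit: "%"
    value_type: quantity
    sources: [EHR]
    inferred: true
  - id: SerumCreatinine
    label: Serum creatinine
    kind: lab-result
    resource_type: Observation
    codings:
      - {system: LOINC, code: "2160-0", display: "Creatinine [Mass/volume] in Serum or Plasma"}
    unit: mg/dL
    value_type: quantity
    sources: [EHR]
  - id: HypertensionDiagnosis
    label: Diagnosed essential hypertension
    kind: diagnosis
    resource_type: Condition
    codings:
      - {system: ICD-10, code: I10, display: "Essential (primary) hypertension"}
    value_type: boolean
    sources: [EHR, AICP]
  - id: Asthma
    label: Asthma
    kind: diagnosis
    resource_type: Condition
    codings:
      - {system: ICD-10, code: J45, display: Asthma}
    value_type: boolean
    sources: [EHR]
    inferred: true
  - id: AVBlock
    label: High-grade sinoatrial or atrioventricular block
    kind: diagnosis
    resource_type: Condition
    codings:
      - {system: ICD-10, code: I44, display: Atrioventricular and left bundle-branch block}
      - {system: ICD-10, code: I45.5, display: Other specified heart block}
    value_type: boolean
    sources: [EHR]
    inferred: true
  - id: CKDDiagnosis
    label: Chronic kidney disease
    kind: diagnosis
    resource_type: Condition
    codings:
      - {system: ICD-10, code: N18, display: Chronic kidney disease}
    value_type: boolean
    sources: [EHR]
    inferred: true
  - id: SentHomeForConfirmation
    label: Sent home for diagnosis confirmation (short-term self-monitoring)
    kind: assessment
    resource_type: Observation
    codings:
      - {system: "http://kroniq.srdc.com.tr/fhir/CodeSystem/concept-id", code: SentHomeForConfirmation}
    value_type: boolean
    sources: [AICP]
  - id: SmokingStatus
    label: Smoking status
    kind: assessment
    resource_type: Observation
    codings:
      - {system: LOINC, code: "72166-2", display: Tobacco smoking status}
    value_type: coded
    value_set:
      - {system: LOINC, code: LA18976-3, display: Current every day smoker}
      - {system: LOINC, code: LA15920-4, display: Former smoker}
      - {system: LOINC, code: LA18978-9, display: Never smoker}
    sources: [AICP, PEP]
  - id: Diuretic
    label: Diuretic therapy
    kind: medication
    resource_type: MedicationStatement
    codings:
      - {system: ATC, code: C03, display: Diuretics}
    value_type: boolean
    sources: [EHR]
  - id: AceiArb
    label: ACE inhibitor / angiotensin II receptor blocker therapy
    kind: medication
    resource_type: MedicationStatement
    codings:
      - {system: ATC, code: C09, display: Agents acting on the renin-angiotensin system}
    value_type: boolean
    sources: [EHR]
  - id: Ccb
    label: Calcium channel blocker therapy
    kind: medication
    resource_type: MedicationStatement
    codings:
      - {system: ATC, code: C08, display: Calcium channel blockers}
    value_type: boolean
    sources: [EHR]
  - id: BetaBlocker
    label: Beta-blocking agent therapy
    kind: medication
    resource_type: MedicationStatement
    codings:
      - {system: ATC, code: C07, display: Beta blocking agents}
    value_type: boolean
    sources: [EHR]
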