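# Inferred autofill card: CKD suggestion when eGFR < 60 mL/min.
card_id: CARD CKD
summary: "Consider CKD diagnosis: the patient's eGFR value is less than 60 mL/min."
source:
  label: CAREPATH best practice guideline
  citation: "Holistic patient-centered CAREPATH best practice guideline, Chapter 12.2"
indicator: info
inferred: true
suggestions:
  - label: "Diagnose chronic kidney disease."
    actions:
      - type: create
        kind: autofill
        description: "Record a diagnosis of chronic kidney disease based on the latest eGFR result."
        resource:
          resourceType: Condition
          clinicalStatus:
            coding:
              - system: "http://terminology.hl7.org/CodeSystem/condition-clinical"
                code: active
          code:
            coding:
              - system: "http://hl7.org/fhir/sid/icd-10"
                code: N18
                display: "Chronic kidney disease"
          subject:
            display: Patient
          recordedDate: "{{Today}}"
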