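# Inferred autofill card: hyperkalemia when potassium > 5.5 mmol/L.
card_id: CARD HYPERKALEMIA
summary: "Consider diagnosing Hyperkalemia: the patient's potassium level is more than 5.5 mmol/L."
source:
  label: CAREPATH best practice guideline
  citation: "Holistic patient-centered CAREPATH best practice guideline, Chapter 12.3.2"
indicator: info
inferred: true
suggestions:
  - label: "Diagnose hyperkalemia."
    actions:
      - type: create
        kind: autofill
        description: "Record a diagnosis of hyperkalemia based on the latest serum potassium result."
        resource:
          resourceType: Condition
          clinicalStatus:
            coding:
              - system: "http://terminology.hl7.org/CodeSystem/condition-clinical"
                code: active
          code:
            coding:
              - system: "http://hl7.org/fhir/sid/icd-10"
                code: E87.5
                display: Hyperkalemia
          subject:
            display: Patient
          recordedDate: "{{Today}}"
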