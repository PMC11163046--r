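# Inferred autofill card: bradycardia when heart rate < 60 /min.
card_id: CARD BRADYCARDIA
summary: "Consider diagnosing Bradycardia: the patient's heart rate is less than 60 bpm."
source:
  label: CAREPATH best practice guideline
  citation: "Holistic patient-centered CAREPATH best practice guideline, Chapter 12.3.2, Table 2"
indicator: info
inferred: true
suggestions:
  - label: "Diagnose bradycardia."
    actions:
      - type: create
        kind: autofill
        description: "Record a diagnosis of bradycardia based on the latest heart-rate measurement."
        resource:
          resourceType: Condition
          clinicalStatus:
            coding:
              - system: "http://terminology.hl7.org/CodeSystem/condition-clinical"
                code: active
          code:
            coding:
              - system: "http://snomed.info/sct"
                code: "48867003"
                display: Bradycardia
          subject:
            display: Patient
          recordedDate: "{{Today}}"
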