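# Inferred autofill card: suggest recording the hypertension diagnosis once
# elevated BP persists after home confirmation.
card_id: CARD DIAGNOSE-HTN
summary: "Consider diagnosing the patient as hypertensive."
detail: >-
  The patient was sent home for diagnosis confirmation and the latest office
  blood pressure remains elevated; the guideline recommends diagnosing the
  patient as hypertensive.
source:
  label: CAREPATH best practice guideline
  citation: "Holistic patient-centered CAREPATH best practice guideline, Chapter 12.2 [pp. 40]"
indicator: info
inferred: true
suggestions:
  - label: "Diagnose the patient as hypertensive."
    actions:
      - type: create
        kind: autofill
        description: "Record a diagnosis of essential (primary) hypertension."
        resource:
          resourceType: Condition
          clinicalStatus:
            coding:
              - system: "http://terminology.hl7.org/CodeSystem/condition-clinical"
                code: active
          code:
            coding:
              - system: "http://hl7.org/fhir/sid/icd-10"
                code: I10
                display: "Essential (primary) hypertension"
          subject:
            display: Patient
          recordedDate: "{{Today}}"
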