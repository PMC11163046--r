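# Inferred autofill card: severe LV dysfunction when LVEF < 40 %.
card_id: CARD LOW-LVEF
summary: "Consider severe left ventricular dysfunction: the patient's ejection fraction is less than 40%."
source:
  label: CAREPATH best practice guideline
  citation: "Holistic patient-centered CAREPATH best practice guideline, Chapter 12.3.2"
indicator: info
inferred: true
suggestions:
  - label: "Record severe left ventricular dysfunction."
    actions:
      - type: create
        kind: autofill
        description: "Record severe left ventricular dysfunction based on the latest ejection-fraction measurement."
        resource:
          resourceType: Condition
          clinicalStatus:
            coding:
              - system: "http://terminology.hl7.org/CodeSystem/condition-clinical"
                code: active
          code:
            coding:
              - system: "http://snomed.info/sct"
                code: "134401001"
                display: "Left ventricular systolic dysfunction"
          subject:
            display: Patient
          recordedDate: "{{Today}}"
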