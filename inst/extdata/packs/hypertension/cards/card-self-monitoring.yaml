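# Inferred from the diagnosis flowchart: short-term BP self-monitoring for
# an undiagnosed patient with an elevated office reading.
card_id: CARD SELF-MONITORING
summary: "Recommend short-term self-monitoring of blood pressure levels to confirm hypertension diagnosis."
detail: >-
  The patient has an elevated office blood pressure and has not yet been
  diagnosed hypertensive. Short-term home self-monitoring of blood pressure
  is recommended before confirming the diagnosis.
source:
  label: CAREPATH best practice guideline
  citation: "Holistic patient-centered CAREPATH best practice guideline, Chapter 12.2 [pp. 40]"
indicator: info
inferred: true
suggestions:
  - label: "Consider short-term self-monitoring of blood pressure levels."
    actions:
      - type: create
        kind: patient-activity
        description: "Consider short-term self-monitoring of blood pressure levels to confirm hypertension diagnosis."
        resource:
          resourceType: ServiceRequest
          status: draft
          extension:
            - url: "http://kroniq.srdc.com.tr/fhir/StructureDefinition/title"
              valueString: "Self-monitoring of BP"
          intent: proposal
          occurrenceTiming:
            repeat:
              boundsPeriod:
                start: "{{Today}}"
                end: "{{Today + 2 weeks}}"
              frequency: 2
              period: 1
              periodUnit: d
          category:
            - coding:
                - system: "http://www.kroniq.srdc.com.tr/fhir/care-plan-activity-category"
                  code: patient-order
                  display: Patient Order
          authoredOn: "{{Today}}"
          code:
            coding:
              - system: "http://loinc.org"
                code: "85354-9"
                display: "Blood pressure panel"
          performer:
            - display: Patient
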