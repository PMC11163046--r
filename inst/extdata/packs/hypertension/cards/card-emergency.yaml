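# Inferred emergency-referral card: clinic BP exceeds 180/110 mmHg.
card_id: CARD EMERGENCY
summary: "Referral to emergency services is advised: clinic blood pressure exceeds 180/110 mmHg."
source:
  label: CAREPATH best practice guideline
  citation: "Holistic patient-centered CAREPATH best practice guideline, Chapter 12.3.2"
indicator: critical
inferred: true
suggestions:
  - label: "Refer the patient to emergency services."
    actions:
      - type: create
        kind: referral
        description: "Immediate referral to emergency services for blood pressure exceeding 180/110 mmHg."
        resource:
          resourceType: ServiceRequest
          status: draft
          extension:
            - url: "http://kroniq.srdc.com.tr/fhir/StructureDefinition/title"
              valueString: "Referral to emergency services"
          intent: proposal
          occurrenceDateTime: "{{Today}}"
          category:
            - coding:
                - system: "http://www.kroniq.srdc.com.tr/fhir/care-plan-activity-category"
                  code: referral
                  display: "Patient referral to specialist"
          authoredOn: "{{Today}}"
          text:
            status: generated
            div: "Referral to emergency services: clinic blood pressure exceeds 180/110 mmHg"
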