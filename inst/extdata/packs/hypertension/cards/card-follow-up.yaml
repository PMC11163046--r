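# Inferred from the diagnosis flowchart: follow-up appointment to confirm
# the diagnosis after 2-4 weeks (earliest bound used for the date; the
# range is kept in the description).
card_id: CARD FOLLOW-UP
summary: "Set a follow-up appointment to confirm hypertension diagnosis after 2–4 weeks."
source:
  label: CAREPATH best practice guideline
  citation: "Holistic patient-centered CAREPATH best practice guideline, Chapter 12.2 [pp. 40]"
indicator: info
inferred: true
suggestions:
  - label: "Consider setting a follow-up appointment to confirm diagnosis after 2–4 weeks."
    actions:
      - type: create
        kind: appointment
        description: "Consider setting a follow-up appointment to confirm hypertension diagnosis after 2–4 weeks."
        resource:
          resourceType: Appointment
          extension:
            - url: "http://kroniq.srdc.com.tr/fhir/StructureDefinition/title"
              valueString: "Follow-up appointment to confirm hypertension diagnosis after 2–4 weeks"
          description: "Follow-up appointment to confirm hypertension diagnosis after 2–4 weeks."
          status: proposed
          start: "{{Today + 2 weeks}}"
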