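# Inferred from the diagnosis flowchart: normal categorization.
card_id: CARD NORMAL-BP
summary: "Blood pressure should be categorized as normal."
detail: >-
  The latest office blood pressure is below 130/85 mmHg; the guideline
  recommends categorizing the patient's blood pressure as normal.
source:
  label: CAREPATH best practice guideline
  citation: "Holistic patient-centered CAREPATH best practice guideline, Chapter 12.2 [pp. 40]"
indicator: info
inferred: true
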