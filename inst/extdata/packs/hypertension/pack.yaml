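name: hypertension
version: "1.0.0"
section: Hypertension
metadata:
  notes: >
    Reference content pack for the hypertension section of the consensus
    guideline. Cards printed in the published specification tables
    (CARD 4, 7, 11, 18, 21, 31, 38) are encoded field-for-field with codes
    normalized to canonical form; cards required by the diagnosis flowchart,
    the measurement-driven (autofill) thresholds and the emergency referral
    are authored here and marked inferred. The remainder of the published
    55-card hypertension inventory exists only in supplementary material and
    is deliberately not invented.
  aspirational_counts:
    rules_section_total: 52
    cards_section_total: 55
  threshold_notes: >
    The diagnosis flowchart narrative says "above 140 mmHg" while the
    categorization card gives grade 1 as "140-159"; this pack uses >= 140,
    consistent with the printed category intervals.
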