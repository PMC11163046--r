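# One CDS-Hooks endpoint per (section, purpose category) pair with rules.
# Prefetch templates are FHIR search strings over the patient data store;
# they may reference only {{context.patientId}}.
services:
  - id: hypertension-diagnosis
    hook: patient-view
    title: Hypertension diagnosis support
    description: Blood-pressure categorization, diagnosis confirmation workflow and measurement-driven diagnosis suggestions.
    prefetch:
      patient: "Patient?patient={{context.patientId}}"
      conditions: "Condition?patient={{context.patientId}}"
      bpPanel: "Observation?patient={{context.patientId}}&code=http://loinc.org|85354-9&_sort=-date&_count=1"
      sbp: "Observation?patient={{context.patientId}}&code=http://loinc.org|8480-6&_sort=-date&_count=1"
      dbp: "Observation?patient={{context.patientId}}&code=http://loinc.org|8482-4&_sort=-date&_count=1"
      heartRate: "Observation?patient={{context.patientId}}&code=http://loinc.org|8867-4&_sort=-date&_count=1"
      potassium: "Observation?patient={{context.patientId}}&code=http://loinc.org|2823-3&_sort=-date&_count=1"
      egfr: "Observation?patient={{context.patientId}}&code=http://loinc.org|33914-3&_sort=-date&_count=1"
      lvef: "Observation?patient={{context.patientId}}&code=http://loinc.org|10230-1&_sort=-date&_count=1"
      sentHomeFlag: "Observation?patient={{context.patientId}}&code=http://kroniq.srdc.com.tr/fhir/CodeSystem/concept-id|SentHomeForConfirmation&_sort=-date&_count=1"
    rules:
      - Hypertension 1
      - Hypertension 2
      - Hypertension 3
      - Hypertension 4
      - Hypertension 5
      - Hypertension 6
      - Hypertension 7
      - Hypertension 8
      - Hypertension 9
      - Hypertension 10
  - id: hypertension-goal-management
    hook: patient-view
    title: Hypertension goal management
    description: Personalized blood-pressure target suggestions.
    prefetch:
      conditions: "Condition?patient={{context.patientId}}"
    rules:
      - Hypertension 11
  - id: hypertension-lifestyle-advice
    hook: patient-view
    title: Hypertension lifestyle advice
    description: Lifestyle interventions and education materials for high-normal or hypertensive patients.
    prefetch:
      conditions: "Condition?patient={{context.patientId}}"
      bpPanel: "Observation?patient={{context.patientId}}&code=http://loinc.org|85354-9&_sort=-date&_count=1"
      sbp: "Observation?patient={{context.patientId}}&code=http://loinc.org|8480-6&_sort=-date&_count=1"
      dbp: "Observation?patient={{context.patientId}}&code=http://loinc.org|8482-4&_sort=-date&_count=1"
      smokingStatus: "Observation?patient={{context.patientId}}&code=http://loinc.org|72166-2&_sort=-date&_count=1"
    rules:
      - Hypertension 12
  - id: hypertension-drug-treatment
    hook: patient-view
    title: Hypertension drug treatment
    description: Medication therapy escalation guidance.
    prefetch:
      conditions: "Condition?patient={{context.patientId}}"
      bpPanel: "Observation?patient={{context.patientId}}&code=http://loinc.org|85354-9&_sort=-date&_count=1"
      sbp: "Observation?patient={{context.patientId}}&code=http://loinc.org|8480-6&_sort=-date&_count=1"
      dbp: "Observation?patient={{context.patientId}}&code=http://loinc.org|8482-4&_sort=-date&_count=1"
      medicationStatements: "MedicationStatement?patient={{context.patientId}}"
      medicationRequests: "MedicationRequest?patient={{context.patientId}}"
    rules:
      - Hypertension 13
  - id: hypertension-adverse-events
    hook: patient-view
    title: Hypertension adverse events and contraindications
    description: Compelling side-effect warnings for antihypertensive drug classes.
    prefetch:
      conditions: "Condition?patient={{context.patientId}}"
      heartRate: "Observation?patient={{context.patientId}}&code=http://loinc.org|8867-4&_sort=-date&_count=1"
      medicationStatements: "MedicationStatement?patient={{context.patientId}}"
      medicationRequests: "MedicationRequest?patient={{context.patientId}}"
    rules:
      - Hypertension 14
  - id: hypertension-complication-referral
    hook: patient-view
    title: Hypertension complication management and referrals
    description: Resistant-hypertension management and emergency referral.
    prefetch:
      conditions: "Condition?patient={{context.patientId}}"
      bpPanel: "Observation?patient={{context.patientId}}&code=http://loinc.org|85354-9&_sort=-date&_count=1"
      sbp: "Observation?patient={{context.patientId}}&code=http://loinc.org|8480-6&_sort=-date&_count=1"
      dbp: "Observation?patient={{context.patientId}}&code=http://loinc.org|8482-4&_sort=-date&_count=1"
      medicationStatements: "MedicationStatement?patient={{context.patientId}}"
    rules:
      - Hypertension 15
      - Hypertension 16
  - id: hypertension-next-visit
    hook: patient-view
    title: Hypertension next-visit planning
    description: Follow-up scheduling for treated patients not yet at target.
    prefetch:
      conditions: "Condition?patient={{context.patientId}}"
      bpPanel: "Observation?patient={{context.patientId}}&code=http://loinc.org|85354-9&_sort=-date&_count=1"
      sbp: "Observation?patient={{context.patientId}}&code=http://loinc.org|8480-6&_sort=-date&_count=1"
      dbp: "Observation?patient={{context.patientId}}&code=http://loinc.org|8482-4&_sort=-date&_count=1"
      creatinine: "Observation?patient={{context.patientId}}&code=http://loinc.org|2160-0&_sort=-date&_count=1"
      medicationStatements: "MedicationStatement?patient={{context.patientId}}"
    rules:
      - Hypertension 17
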