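# cdscards

Clinical guidelines say things like *"if the patient's office blood
pressure exceeds 140/90 mmHg and they have not yet been sent home for
confirmation, recommend short-term self-monitoring and a follow-up
appointment in 2–4 weeks"*. Turning such narrative guidance into software
that runs inside a clinician's workflow requires three things: a machine
representation of the patient record, a declarative encoding of the rules
with every clinical parameter bound to standard terminologies, and a wire
format for delivering the resulting suggestions. `cdscards` implements this
stack in R:

- a minimal **HL7 FHIR R4 data model** (Patient, Condition, Observation,
  MedicationStatement/Request, Goal, ServiceRequest, Appointment,
  CommunicationRequest) with JSON readers/writers and schema-subset
  validation;
- a **clinical-concept registry** binding rule parameters (e.g. `[SBP]`) to
  FHIR resource types, LOINC/SNOMED CT/ICD-10/ATC codes, UCUM units and
  value sets;
- a **rule engine** evaluating a closed condition grammar (comparisons over
  latest values, diagnosis/medication membership, workflow flags, boolean
  composition) with **Kleene three-valued logic** — a missing measurement
  makes a condition *unknown*, and unknown suppresses guidance rather than
  guessing;
- a **card engine** rendering CDS-Hooks information and suggestion cards
  from declarative templates, resolving `{{Today + N days|weeks|months}}`
  date placeholders with month-end clamping, and embedding validated FHIR
  resources (goals, lab orders, referrals, appointments, education
  materials, medications) that can populate a care plan;
- a **CDS-Hooks service layer**: discovery document, FHIR-query prefetch
  resolution over an in-process bundle store, and service invocation
  returning conformant card responses;
- a reference **hypertension content pack** encoding office BP grading
  (normal / high-normal / grade 1–3 via per-component interval tables and
  max-severity combination), the diagnosis confirmation workflow,
  resistant-hypertension management, measurement-driven ("autofill")
  diagnosis suggestions (bradycardia HR < 60 /min, hyperkalemia
  K > 5.5 mmol/L, severe LV dysfunction LVEF < 40 %, CKD
  eGFR < 60 mL/min), beta-blocker contraindication warnings and emergency
  referral (BP > 180/110 mmHg);
- a seeded **synthetic-patient generator** so every service and card is
  exercisable without any external data.

## Worked example

Generate a resistant-hypertension patient (diagnosed hypertensive, three
antihypertensive classes including a diuretic, BP still uncontrolled) and
invoke every shipped service:

```r
library(cdscards)

bundle <- generate_scenario("resistant-hypertension", seed = 7)
bundle
#> <fhir_bundle> Patient/patient-1 + 7 resources

invoke_all(hypertension_pack(), bundle, now = as.Date("2024-06-01"))
#> # A tibble: 5 × 3
#>   service_id                         card_id summary
#>   <chr>                              <chr>   <chr>
#> 1 hypertension-complication-referral CARD 18 Management of resistant hypertensi…
#> 2 hypertension-drug-treatment        CARD 31 Consider triple combination of ACE…
#> 3 hypertension-goal-management       CARD 11 Systolic BP should be targeted to …
#> 4 hypertension-lifestyle-advice      CARD 7  Offer Lifestyle interventions for …
#> 5 hypertension-next-visit            CARD 21 Arrange a follow-up visit in 1 mon…
```

The engine recognized resistant hypertension (CARD 18: self-monitoring
order, follow-up appointment at now + 2 weeks, cardiology referral coded
SNOMED CT 175651000), suggested escalation to triple therapy (CARD 31, ATC
class C07), BP goals (CARD 11: systolic 130–140 mmHg, diastolic < 80 mmHg,
due in 3 months), lifestyle education materials (CARD 7) and a monthly
follow-up with a creatinine order (CARD 21). A single full CDS-Hooks
exchange looks like:

```r
req  <- cds_request(patient_id = "patient-1")
resp <- invoke(hypertension_pack(), "hypertension-complication-referral",
               req, bundle, now = as.Date("2024-06-01"))
validate_json_schema(resp, cds_hooks_schema("response"))  # 0 rows = conformant
```

Pure decision functions are exported too:

```r
categorize_bp(152, 96)
#> [1] "grade-1"
```

A command-line interface (`inst/exec/cdscards`) wraps the same functions:
`evaluate`, `validate`, `trace`, `generate`, `discovery`.

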