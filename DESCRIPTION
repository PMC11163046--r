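Package: cdscards
Title: Declarative Clinical Decision Support Services over HL7 FHIR R4
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A CDS-Hooks-compliant clinical decision support engine that
    evaluates declarative, terminology-bound guideline rules against HL7
    FHIR R4 patient records and returns information and suggestion cards
    whose embedded FHIR resources (goals, lab orders, referrals,
    appointments, education materials, medications) can populate a care
    plan. Ships a reference hypertension content pack (blood-pressure
    grading, diagnosis workflow, resistant-hypertension management,
    autofill diagnosis suggestions, beta-blocker contraindication
    warnings) together with a seeded synthetic-patient generator so every
    service is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    purrr,
    tibble,
    dplyr,
    lubridate,
    rlang,
    ggplot2,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
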