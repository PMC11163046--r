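---
title: "A declarative CDS-Hooks engine for guideline-based care planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A declarative CDS-Hooks engine for guideline-based care planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdscards)
```

## The problem

Evidence-based guidelines describe care as prose; clinical decision
support (CDS) needs the same content as data: patient parameters bound to
terminologies, conditions that can be evaluated mechanically, and outputs
that a care-planning application can insert into a record. `cdscards`
separates these concerns into a generic engine (FHIR data model, concept
registry, expression evaluation, card rendering, CDS-Hooks service layer)
and declarative *content packs* — YAML documents holding the concepts,
rules, card templates and service descriptors for one guideline section.
The shipped pack covers hypertension management for older multimorbid
patients; the schema is section-agnostic.

## Patient data model

Nine FHIR R4 resource types are supported — the ones guideline cards and
their inputs actually use. A `fhir_bundle` holds exactly one Patient plus
that patient's resources; `parse_bundle()` accepts a FHIR `Bundle`
(collection) or a flat resource array, validates a per-type schema subset
(required attributes, ISO 8601 dates, URL-bearing extensions, supported
code systems, finite UCUM quantities), and preserves unknown attributes
opaquely. `serialize_bundle()` emits resources in canonical (type, id)
order so parse ∘ serialize is the identity.

Two conventions are deliberate divergences from source tables transcribed
into the pack:

- **code normalization** — typeset codes with thousands separators and
  en-dashes ("85,354–9") are stored and emitted canonically ("85354-9"),
  because terminology servers and FHIR validators require canonical codes;
- **canonical FHIR spelling** — the engine emits `occurrenceDateTime` /
  `occurrenceTiming`, and the medication-suggestion card embeds a
  `MedicationRequest` with `status`/`intent`/`medicationCodeableConcept`
  rather than the table's `lifecycleStatus`/`Medication.code` rows, for
  interoperability.

Blood pressure is accepted both as a LOINC 85354-9 panel with 8480-6 /
8482-4 components and as standalone observations; value selection unifies
the two shapes.

## Three-valued evaluation

Rule conditions form a closed AST: comparisons of a concept's latest value
against a literal, presence tests, active-diagnosis and ATC-prefix
medication membership, boolean workflow flags, and And/Or/Not. A general
FHIRPath interpreter was considered and rejected: the printed rules need
only these forms, and a closed grammar is exhaustively testable.

Missing data is the norm in real records, so evaluation uses Kleene
three-valued logic: a comparison over an absent measurement is *unknown*;
`unknown OR true = true`, `unknown AND false = false`,
`NOT unknown = unknown`. Cards fire only on *true* — a clinician-in-the-loop
design should suggest actions only when supporting data exists, so unknown
suppresses the card. Three leaf kinds deliberately resolve absence to
*false* instead: an absent Condition record (no diagnosis on file means
not diagnosed), absent medication records, and never-recorded workflow
flags (a patient never "sent home for diagnosis confirmation" simply has
no such assessment; treating that as unknown would block the entire
diagnosis branch for every new patient).

Latest-value selection takes the maximal effective time regardless of age
(a per-concept `max_age_days` override exists for packs that want a
lookback window; the default is unlimited because the source guidance is
silent). Ties on the timestamp break toward the lexicographically greater
resource id. Units are never converted: the observation's UCUM string must
equal the concept's unit exactly, because silent conversion risks
dosing-grade errors; a mismatch is a hard error, not unknown.

## Cards and placeholders

Card templates mirror the published specification tables field for field:
summary (≤ 140 characters), optional markdown detail, a source citation,
an indicator, and suggestions whose actions embed parametrized FHIR
resources. Information cards have no suggestions by definition. Within a
suggestion all actions are accepted together, so rendering always emits
the full action list. Where a guideline range is printed ("after 2–4
weeks") the earliest bound is used for the concrete date and the range is
kept in the description text.

Placeholders follow a small grammar — `{{Today}}`,
`{{Today + N days|weeks|months}}`, `{{name}}` for caller bindings — with
proleptic-Gregorian arithmetic and month-end clamping
(`2024-01-31 + 1 month → 2024-02-29`), the least-surprise calendar
convention. Rendering is pure (templates are reusable across patients),
validates every embedded resource, and attaches a fresh UUID; everything
else is deterministic for fixed inputs.

Indicator levels are an engine convention, since the source content never
assigns them: `info` by default, `warning` for contraindication cards,
`critical` for the emergency referral. "Autofill" cards — suggestions to
record a diagnosis implied by a recent measurement — are not a CDS-Hooks
concept; they are encoded as suggestion cards whose single action creates
a Condition, the closest conformant representation.

## Services and prefetch

One service exists per (section, purpose category) pair with rules:
diagnosis, lifestyle advice, goal management, drug treatment, adverse
events/contraindications, information & guidance, symptom recording,
complication management & referrals, next-visit planning. All services
default to the `patient-view` hook (page-open triggering maps most closely
to it; packs may override). The engine is trigger-agnostic and evaluates
every attached rule per invocation — triggering belongs to the CDS client.

Prefetch templates are FHIR search strings over the in-process bundle
store, supporting `patient`, `code` (`system|code`), `status`, `_sort` by
date and `_count`, and may reference only `{{context.patientId}}`. A
startup validator proves *prefetch completeness*: every concept used by a
service's rules is retrievable through at least one of its prefetch
entries (the BP panel code covers its component concepts). Client-supplied
prefetch overrides server-side resolution, per CDS-Hooks. The "now" used
for date placeholders is injectable so rendered dates are reproducible.
There is no HTTP listener in the package: `discovery()` and `invoke()` are
pure request/response handlers producing the CDS-Hooks wire format, which
any HTTP front end can wrap; authentication is out of scope.

## The hypertension pack

Office BP grading maps each component through inclusive-lower-bound
intervals (systolic 130/140/160/180; diastolic 85/90/100/110) and returns
the more severe component category. The source prose never states a
precedence for disagreeing components; max severity is the standard ESC
convention and makes the function total — it is isolated in
`categorize_bp()` and verified exhaustively against an independent
interval-table oracle on the full 60–260 × 30–160 mmHg integer grid.

Threshold strictness is taken literally from the guidance wording: "less
than 60", "more than 5.5", "less than 40%", "less than 60 mL/min" and
"exceeds 180/110" are strict inequalities, so the boundary values 60 /min,
5.5 mmol/L, 40 %, 60 mL/min, 180/110 mmHg do not trigger. The narrative
"above 140 mmHg" conflicts with the printed grade-1 interval "140–159";
the pack uses ≥ 140, consistent with the intervals, and records the
ambiguity in its metadata.

The pack ships the seven cards printed in the source tables
(field-for-field, codes normalized) plus the minimal set of inferred cards
the diagnosis flowchart, autofill thresholds and emergency referral
require; inferred cards are flagged `inferred: true` in their templates
and the remainder of the published 55-card inventory is deliberately not
invented. The resistant-hypertension rule requires the three named drug
classes (diuretic C03, ACEi/ARB C09, CCB C08) as medication-membership
conjuncts because the closed grammar has no "count distinct ATC classes"
primitive; this matches the guidance's "three or more drugs, which should
include a diuretic, typically an ACE inhibitor or an ARB, and a CCB".

## Synthetic patients

`generate_scenario(name, seed, now)` builds deterministic bundles for ten
named archetypes (normal BP through resistant hypertension and the four
autofill findings). Values are drawn uniformly inside clinically plausible
per-scenario ranges — e.g. grade-1 presentation draws the latest systolic
reading from 140–159 mmHg and diastolic from 90–99 mmHg; hyperkalemia
draws potassium on a 0.1 grid from 5.6–7.0 mmol/L. The generator's job is
coverage of rule branches, not epidemiology: it makes no attempt at
realistic population distributions, longitudinal trajectories, comorbidity
correlations, measurement noise or coding errors, so passing scenario
contracts demonstrates the engine's branch behaviour, not performance on
real EHR data. Timestamps are generated relative to the injectable `now`
(default 2024-06-01) so latest-value selection is reproducible, and the
generator uses a private RNG stream that leaves the caller's seed state
untouched.

```{r}
list_scenarios()
```

## Verification

The test suite verifies, among other properties: round-trip identity of
parse/serialize on all generated scenarios; exhaustive agreement of the BP
grading with its oracle (~27,000 grid points, well under a second);
the Kleene truth tables against a brute-force lookup over all 27
three-leaf states; golden-field reproduction of the seven published cards;
strictness of every threshold by boundary sweeps; schema conformance of
discovery and response payloads against the CDS-Hooks JSON schemas bundled
under `inst/schemas` (checked with the package's own JSON-Schema-subset
validator); prefetch completeness of the shipped pack; and the
scenario-to-card contract across 25 seeds per scenario. These sizes keep
the whole suite in the tens of seconds on one CPU while exercising every
rule branch.

```{r, fig.width = 6, fig.height = 4}
plot_bp_grid()
```

## Known limitations

The engine targets FHIR R4 only and performs no profile/StructureDefinition
validation; prefetch emulates only the search parameters its templates
need; there is no temporal logic (trends, deltas) and no cross-encounter
aggregation; terminology bindings are static (no terminology-server
lookups or code-system version pinning); and only the hypertension section
ships as content — the schema supports the other guideline sections, but
their rule inventories are not reproduced here.
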