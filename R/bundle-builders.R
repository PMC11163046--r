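# Small constructors for the FHIR resources patient scenarios are built
# from. These are the same shapes parse_bundle() accepts, so generated
# bundles round-trip through JSON.

#' FHIR resource builders for patient bundles
#'
#' Thin constructors for the resource shapes the engine consumes: a Patient,
#' quantity/boolean Observations (including the blood-pressure panel with
#' its two components), active Conditions and ATC-coded medication
#' statements.
#'
#' @param id Resource id (unique within the bundle).
#' @param patient_id Id of the bundle's Patient resource.
#' @param system,code,display Primary coding of the resource.
#' @param value,unit Quantity value and UCUM unit.
#' @param date Effective ISO date.
#' @param gender,birth_date Patient demographics.
#' @param sbp,dbp Panel component values in mmHg.
#' @param status Resource status.
#' @return A `fhir_resource`.
#' @name bundle-builders
NULL

#' @rdname bundle-builders
#' @export
build_patient <- function(id = "patient-1", gender = "female",
                          birth_date = "1948-03-12") {
  fhir_resource("Patient", id = id,
                attributes = list(gender = gender, birthDate = birth_date))
}

#' @rdname bundle-builders
#' @export
build_observation <- function(id, system, code, display, value, unit,
                              date, patient_id = "patient-1") {
  fhir_resource("Observation", id = id, attributes = list(
    status = "final",
    code = list(coding = list(list(system = system, code = code,
                                   display = display))),
    subject = list(reference = paste0("Patient/", patient_id)),
    effectiveDateTime = date,
    valueQuantity = list(value = value, unit = unit,
                         system = "http://unitsofmeasure.org", code = unit)
  ))
}

#' @rdname bundle-builders
#' @export
build_flag_observation <- function(id, code, value, date,
                                   patient_id = "patient-1") {
  fhir_resource("Observation", id = id, attributes = list(
    status = "final",
    code = list(coding = list(list(
      system = "http://kroniq.srdc.com.tr/fhir/CodeSystem/concept-id",
      code = code
    ))),
    subject = list(reference = paste0("Patient/", patient_id)),
    effectiveDateTime = date,
    valueBoolean = isTRUE(value)
  ))
}

#' @rdname bundle-builders
#' @export
build_bp_panel <- function(id, sbp, dbp, date, patient_id = "patient-1") {
  comp <- function(code, display, value) {
    list(
      code = list(coding = list(list(system = "http://loinc.org",
                                     code = code, display = display))),
      valueQuantity = list(value = value, unit = "mm[Hg]",
                           system = "http://unitsofmeasure.org",
                           code = "mm[Hg]")
    )
  }
  fhir_resource("Observation", id = id, attributes = list(
    status = "final",
    code = list(coding = list(list(system = "http://loinc.org",
                                   code = "85354-9",
                                   display = "Blood pressure panel"))),
    subject = list(reference = paste0("Patient/", patient_id)),
    effectiveDateTime = date,
    component = list(
      comp("8480-6", "Systolic blood pressure", sbp),
      comp("8482-4", "Diastolic blood pressure", dbp)
    )
  ))
}

#' @rdname bundle-builders
#' @export
build_condition <- function(id, system, code, display,
                            patient_id = "patient-1", status = "active") {
  fhir_resource("Condition", id = id, attributes = list(
    clinicalStatus = list(coding = list(list(
      system = "http://terminology.hl7.org/CodeSystem/condition-clinical",
      code = status
    ))),
    code = list(coding = list(list(system = system, code = code,
                                   display = display))),
    subject = list(reference = paste0("Patient/", patient_id))
  ))
}

#' @rdname bundle-builders
#' @export
build_medication_statement <- function(id, code, display,
                                       patient_id = "patient-1",
                                       status = "active") {
  fhir_resource("MedicationStatement", id = id, attributes = list(
    status = status,
    medicationCodeableConcept = list(coding = list(list(
      system = "http://www.whocc.no/atc", code = code, display = display
    ))),
    subject = list(reference = paste0("Patient/", patient_id))
  ))
}
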