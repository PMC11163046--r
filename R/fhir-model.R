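# Minimal HL7 FHIR R4 data model: just the nine resource types that guideline
# cards and their patient inputs use, with JSON readers/writers and a
# per-type schema-subset validator. This is not a general FHIR library;
# unknown attributes are carried opaquely so records survive round trips.

FHIR_RESOURCE_TYPES <- c(
  "Patient", "Condition", "Observation", "MedicationStatement",
  "MedicationRequest", "Goal", "ServiceRequest", "Appointment",
  "CommunicationRequest"
)

# Terminology systems the engine accepts (prefix match for the HL7 and
# project-local namespaces).
SUPPORTED_SYSTEM_PREFIXES <- c(
  "http://loinc.org",
  "http://snomed.info/sct",
  "http://hl7.org/fhir/sid/icd-10",
  "http://www.whocc.no/atc",
  "http://unitsofmeasure.org",
  "http://terminology.hl7.org/",
  "http://hl7.org/fhir/",
  "http://kroniq.srdc.com.tr/",
  "http://www.kroniq.srdc.com.tr/"
)

is_supported_system <- function(system) {
  any(startsWith(system, SUPPORTED_SYSTEM_PREFIXES))
}

# Attribute names that must hold ISO 8601 dates/dateTimes wherever they occur.
FHIR_DATE_FIELDS <- c(
  "effectiveDateTime", "authoredOn", "start", "end", "startDate",
  "occurrenceDateTime", "dueDate", "recordedDate", "issued", "onsetDateTime"
)

#' Construct a terminology coding
#'
#' @param system Terminology system URI (LOINC, SNOMED CT, ICD-10, ATC or a
#'   project-local code system).
#' @param code Code within the system; typeset separators (commas,
#'   en-dashes) are normalized to canonical form.
#' @param display Optional human-readable display string.
#' @return A named list with class `fhir_coding`.
#' @export
fhir_coding <- function(system, code, display = NULL) {
  code <- normalize_code(code)
  if (!nzchar(system) || !is_supported_system(system)) {
    cds_abort(paste0("unsupported code system: '", system, "'"),
              "fhir_validation_error")
  }
  if (!nzchar(code) || grepl("\\s", code)) {
    cds_abort("coding code must be non-empty without whitespace",
              "fhir_validation_error")
  }
  out <- list(system = system, code = code)
  if (!is.null(display)) out$display <- display
  structure(out, class = c("fhir_coding", "list"))
}

#' Construct a UCUM-annotated quantity
#'
#' @param value Finite numeric value.
#' @param unit UCUM unit expression (e.g. `"mm[Hg]"`, `"mmol/L"`).
#' @return A named list with class `fhir_quantity`.
#' @export
fhir_quantity <- function(value, unit) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    cds_abort("quantity value must be a finite number", "fhir_validation_error")
  }
  if (!is_valid_ucum(unit)) {
    cds_abort(paste0("invalid UCUM unit: '", unit, "'"),
              "fhir_validation_error")
  }
  structure(
    list(value = value, unit = unit, system = "http://unitsofmeasure.org",
         code = unit),
    class = c("fhir_quantity", "list")
  )
}

#' Construct a resource envelope
#'
#' A resource envelope is one FHIR R4 resource reduced to its type, id and
#' an attribute map kept structurally as parsed from JSON.
#'
#' @param resource_type One of the nine supported FHIR R4 resource types.
#' @param id Resource id (unique within a bundle).
#' @param attributes Named list of FHIR attributes (everything except
#'   `resourceType` and `id`).
#' @return An object of class `fhir_resource`.
#' @export
fhir_resource <- function(resource_type, id = NULL, attributes = list()) {
  if (!resource_type %in% FHIR_RESOURCE_TYPES) {
    cds_abort(
      paste0("unsupported resourceType '", resource_type, "'"),
      "fhir_validation_error"
    )
  }
  structure(
    list(resource_type = resource_type, id = id,
         attributes = normalize_resource_codes(attributes)),
    class = "fhir_resource"
  )
}

# Walk an attribute tree and canonicalize every coding's code. Idempotent.
normalize_resource_codes <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm) && all(c("system", "code") %in% nm) &&
      is.character(x$code)) {
    x$code <- normalize_code(x$code)
    return(x)
  }
  lapply(x, normalize_resource_codes)
}

#' @export
print.fhir_resource <- function(x, ...) {
  cat("<", x$resource_type, "/", x$id %||% "(no id)", "> ",
      length(x$attributes), " attributes\n", sep = "")
  invisible(x)
}

REQUIRED_ATTRIBUTES <- list(
  Patient = character(),
  Condition = c("code", "subject"),
  Observation = c("status", "code"),
  MedicationStatement = c("status", "subject"),
  MedicationRequest = c("status", "intent"),
  Goal = c("lifecycleStatus", "description"),
  ServiceRequest = c("status", "intent"),
  Appointment = c("status"),
  CommunicationRequest = c("status")
)

#' Validate a resource envelope against the per-type schema subset
#'
#' Checks the base-profile requirements the engine relies on: required
#' attributes per type, ISO 8601 dates, URL-bearing extensions, supported
#' code systems and well-formed quantities.
#'
#' @param env A `fhir_resource`.
#' @return A tibble with columns `path` and `message`; zero rows when valid.
#' @export
validate_resource <- function(env) {
  stopifnot(inherits(env, "fhir_resource"))
  v <- list()
  add <- function(path, message) {
    v[[length(v) + 1L]] <<- list(path = path, message = message)
  }
  req <- REQUIRED_ATTRIBUTES[[env$resource_type]]
  for (attr in req) {
    if (is.null(env$attributes[[attr]])) {
      add(attr, paste0("required attribute missing on ", env$resource_type))
    }
  }
  if (env$resource_type %in% c("MedicationStatement", "MedicationRequest") &&
      is.null(env$attributes$medicationCodeableConcept) &&
      is.null(env$attributes$medicationReference)) {
    add("medication[x]", "medicationCodeableConcept or medicationReference required")
  }
  walk_attrs <- function(x, path) {
    if (!is.list(x)) return(invisible(NULL))
    nm <- names(x)
    if (!is.null(nm)) {
      for (field in intersect(nm, FHIR_DATE_FIELDS)) {
        val <- x[[field]]
        if (is.character(val) && !is_iso_datetime(val)) {
          add(paste0(path, field), paste0("not an ISO 8601 date: '", val, "'"))
        }
      }
      if ("extension" %in% nm && is.list(x$extension)) {
        for (i in seq_along(x$extension)) {
          ext <- x$extension[[i]]
          if (is.null(ext$url) || !nzchar(ext$url)) {
            add(paste0(path, "extension[", i, "].url"),
                "extension requires a url")
          }
        }
      }
      if ("coding" %in% nm && is.list(x$coding)) {
        for (i in seq_along(x$coding)) {
          cd <- x$coding[[i]]
          p <- paste0(path, "coding[", i, "]")
          if (is.null(cd$system) || !nzchar(cd$system %||% "")) {
            add(paste0(p, ".system"), "coding requires a system")
          } else if (!is_supported_system(cd$system)) {
            add(paste0(p, ".system"),
                paste0("unsupported code system: ", cd$system))
          }
          if (is.null(cd$code) || !nzchar(cd$code %||% "") ||
              grepl("\\s", cd$code %||% "")) {
            add(paste0(p, ".code"), "coding code must be non-empty, no whitespace")
          }
        }
      }
      for (qf in intersect(nm, c("valueQuantity", "detailQuantity"))) {
        q <- x[[qf]]
        p <- paste0(path, qf)
        if (!is.numeric(q$value %||% NA) || !is.finite(q$value %||% NA)) {
          add(paste0(p, ".value"), "quantity value must be finite")
        }
        if (!is.null(q$unit) && !is_valid_ucum(q$unit)) {
          add(paste0(p, ".unit"), paste0("invalid UCUM unit: '", q$unit, "'"))
        }
      }
    }
    for (i in seq_along(x)) {
      child <- x[[i]]
      if (is.list(child)) {
        label <- if (!is.null(nm) && nzchar(nm[i] %||% "")) nm[i] else
          paste0("[", i, "]")
        # skip nodes already handled above to avoid duplicate reports
        if (!identical(label, "coding")) {
          walk_attrs(child, paste0(path, label, "."))
        }
      }
    }
    invisible(NULL)
  }
  walk_attrs(env$attributes, "")
  tibble(
    path = vapply(v, `[[`, "", "path"),
    message = vapply(v, `[[`, "", "message")
  )
}

#' Construct a patient bundle
#'
#' @param patient A `fhir_resource` of type Patient.
#' @param resources List of `fhir_resource` objects belonging to the patient.
#' @return An object of class `fhir_bundle` with resources in canonical
#'   (type, id) order.
#' @export
fhir_bundle <- function(patient, resources = list()) {
  stopifnot(inherits(patient, "fhir_resource"),
            patient$resource_type == "Patient")
  ord <- order(
    vapply(resources, `[[`, "", "resource_type"),
    vapply(resources, function(r) r$id %||% "", FUN.VALUE = "")
  )
  structure(
    list(patient = patient, resources = resources[ord]),
    class = "fhir_bundle"
  )
}

#' @export
print.fhir_bundle <- function(x, ...) {
  cat("<fhir_bundle> Patient/", x$patient$id %||% "?", " + ",
      length(x$resources), " resources\n", sep = "")
  invisible(x)
}

#' Parse a FHIR R4 JSON bundle into a patient bundle
#'
#' Accepts either a FHIR `Bundle` (type "collection") or a flat JSON array
#' of resources; exactly one Patient must be present, all subject/patient
#' references must resolve to it, and resource ids must be unique. Unknown
#' attributes are preserved opaquely; unknown resource types are rejected.
#'
#' @param text A JSON string, or a path to a JSON file.
#' @return A validated `fhir_bundle`.
#' @export
parse_bundle <- function(text) {
  if (length(text) == 1L && !grepl("[{\\[]", substr(text, 1, 1)) &&
      file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) cds_abort(
      paste0("malformed JSON: ", conditionMessage(e)), "fhir_parse_error"
    )
  )
  raw <- if (!is.null(names(parsed)) && identical(parsed$resourceType, "Bundle")) {
    lapply(parsed$entry %||% list(), function(e) e$resource)
  } else if (is.null(names(parsed))) {
    parsed
  } else {
    cds_abort("input must be a FHIR Bundle or a resource array",
              "fhir_parse_error")
  }
  envs <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    res <- raw[[i]]
    rt <- res$resourceType
    if (is.null(rt) || !rt %in% FHIR_RESOURCE_TYPES) {
      cds_abort(
        paste0("entry ", i, " (id '", res$id %||% "?",
               "'): unsupported resourceType '", rt %||% "<missing>", "'"),
        "fhir_validation_error"
      )
    }
    attrs <- res[setdiff(names(res), c("resourceType", "id"))]
    envs[[i]] <- fhir_resource(rt, id = res$id, attributes = attrs)
  }
  types <- vapply(envs, `[[`, "", "resource_type")
  if (sum(types == "Patient") != 1L) {
    cds_abort(paste0("bundle must contain exactly one Patient, found ",
                     sum(types == "Patient")), "fhir_validation_error")
  }
  ids <- vapply(envs, function(e) e$id %||% "", FUN.VALUE = "")
  if (any(!nzchar(ids))) {
    cds_abort("every bundle resource needs an id", "fhir_validation_error")
  }
  if (anyDuplicated(ids)) {
    cds_abort(paste0("duplicate resource id(s): ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "fhir_validation_error")
  }
  patient <- envs[[which(types == "Patient")]]
  rest <- envs[types != "Patient"]
  for (env in rest) {
    ref <- env$attributes$subject$reference %||%
      env$attributes$patient$reference
    if (!is.null(ref) && !identical(ref, paste0("Patient/", patient$id))) {
      cds_abort(
        paste0(env$resource_type, "/", env$id,
               ": subject reference '", ref, "' does not resolve to Patient/",
               patient$id),
        "fhir_validation_error"
      )
    }
    viol <- validate_resource(env)
    if (nrow(viol) > 0L) {
      cds_abort(
        paste0(env$resource_type, "/", env$id, ": ",
               paste0(viol$path, ": ", viol$message, collapse = "; ")),
        "fhir_validation_error"
      )
    }
  }
  fhir_bundle(patient, rest)
}

resource_to_json_list <- function(env) {
  c(list(resourceType = env$resource_type),
    if (!is.null(env$id)) list(id = env$id),
    env$attributes)
}

#' Serialize a patient bundle to FHIR R4 JSON
#'
#' Resources are emitted in canonical (resource type, id) order so that
#' `parse_bundle(serialize_bundle(b))` reproduces `b` field for field.
#'
#' @param bundle A `fhir_bundle`.
#' @param path Optional file path; when given, the JSON is also written there.
#' @return The JSON text (invisibly when `path` is given).
#' @export
serialize_bundle <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "fhir_bundle"))
  all_res <- c(list(bundle$patient), bundle$resources)
  for (env in all_res) {
    viol <- validate_resource(env)
    if (nrow(viol) > 0L) {
      cds_abort(
        paste0("cannot serialize invalid ", env$resource_type, "/",
               env$id %||% "?", ": ",
               paste0(viol$path, ": ", viol$message, collapse = "; ")),
        "fhir_validation_error"
      )
    }
  }
  ord <- order(vapply(all_res, `[[`, "", "resource_type"),
               vapply(all_res, function(r) r$id %||% "", FUN.VALUE = ""))
  doc <- list(
    resourceType = "Bundle",
    type = "collection",
    entry = lapply(all_res[ord], function(e) list(
      resource = resource_to_json_list(e)
    ))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

# Extract every coding (system, code) pair from a CodeableConcept-ish node.
codings_of <- function(codeable) {
  if (is.null(codeable)) return(list())
  codeable$coding %||% list()
}

coding_matches <- function(codings, system, code) {
  any(vapply(codings, function(cd) {
    identical(cd$system %||% "", system) &&
      identical(normalize_code(cd$code %||% ""), code)
  }, FUN.VALUE = TRUE))
}
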