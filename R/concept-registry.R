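# The clinical-concept dictionary: each rule parameter (e.g. [SBP]) is bound
# to a FHIR resource type, terminology codings, a UCUM unit, an optional
# value set, and its data sources. Concept files are YAML documents shipped
# inside a content pack.

CONCEPT_KINDS <- c("diagnosis", "symptom", "lab-result", "vital-sign",
                   "assessment", "medication", "procedure")
CONCEPT_VALUE_TYPES <- c("quantity", "boolean", "coded", "text")
CONCEPT_SOURCES <- c("EHR", "AICP", "PEP", "HHMP")

SYSTEM_URIS <- c(
  LOINC = "http://loinc.org",
  SNOMED = "http://snomed.info/sct",
  `ICD-10` = "http://hl7.org/fhir/sid/icd-10",
  ATC = "http://www.whocc.no/atc"
)

resolve_system_uri <- function(system) {
  if (system %in% names(SYSTEM_URIS)) return(unname(SYSTEM_URIS[[system]]))
  if (is_supported_system(system)) return(system)
  cds_abort(paste0("unknown code system: '", system, "'"),
            "concept_schema_error")
}

new_clinical_concept <- function(concept_id, label, kind, resource_type,
                                 codings, unit = NULL,
                                 value_type = "quantity",
                                 value_set = NULL, sources = "EHR",
                                 inferred = FALSE, max_age_days = NULL) {
  err <- function(msg) cds_abort(
    paste0("concept '", concept_id, "': ", msg), "concept_schema_error"
  )
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", concept_id)) err("invalid concept id")
  if (!kind %in% CONCEPT_KINDS) err(paste0("unknown kind '", kind, "'"))
  if (!resource_type %in% FHIR_RESOURCE_TYPES) err("unknown resource type")
  if (!value_type %in% CONCEPT_VALUE_TYPES) err("unknown value type")
  if (length(codings) == 0L) err("at least one coding required")
  if (!all(sources %in% CONCEPT_SOURCES)) err("unknown data source")
  if (value_type == "quantity" && is.null(unit)) {
    err("quantity concepts require a UCUM unit")
  }
  if (!is.null(unit) && !is_valid_ucum(unit)) err("invalid UCUM unit")
  if (value_type == "coded" && length(value_set %||% list()) < 2L) {
    err("coded concepts require a value set with >= 2 members")
  }
  systems <- vapply(codings, `[[`, "", "system")
  if (kind == "medication" &&
      !all(systems == SYSTEM_URIS[["ATC"]])) {
    err("medication concepts must use ATC codings")
  }
  if (kind == "diagnosis" &&
      !all(systems %in% SYSTEM_URIS[c("ICD-10", "SNOMED")])) {
    err("diagnosis concepts must use ICD-10 or SNOMED CT codings")
  }
  structure(
    list(concept_id = concept_id, label = label, kind = kind,
         resource_type = resource_type, codings = codings, unit = unit,
         value_type = value_type, value_set = value_set %||% list(),
         sources = sources, inferred = isTRUE(inferred),
         max_age_days = max_age_days),
    class = "clinical_concept"
  )
}

concept_from_yaml <- function(x) {
  codings <- lapply(x$codings, function(cd) {
    fhir_coding(resolve_system_uri(cd$system), cd$code, cd$display)
  })
  value_set <- lapply(x$value_set, function(cd) {
    fhir_coding(resolve_system_uri(cd$system), cd$code, cd$display)
  })
  new_clinical_concept(
    concept_id = x$id, label = x$label %||% x$id, kind = x$kind,
    resource_type = x$resource_type, codings = codings, unit = x$unit,
    value_type = x$value_type %||% "quantity",
    value_set = if (length(value_set)) value_set,
    sources = unlist(x$sources %||% "EHR"),
    inferred = isTRUE(x$inferred),
    max_age_days = x$max_age_days
  )
}

#' Load a clinical-concept table from a content-pack concept file
#'
#' @param file Path to a YAML concept file.
#' @return A `concept_registry` object (a named list of concepts plus file
#'   provenance).
#' @export
load_concept_table <- function(file) {
  doc <- yaml::read_yaml(file)
  if (is.null(doc$concepts)) {
    cds_abort(paste0(file, ": concept file must have a top-level 'concepts' list"),
              "concept_schema_error")
  }
  concepts <- lapply(doc$concepts, concept_from_yaml)
  ids <- vapply(concepts, `[[`, "", "concept_id")
  if (anyDuplicated(ids)) {
    cds_abort(paste0("duplicate concept id(s): ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "concept_schema_error")
  }
  names(concepts) <- ids
  structure(list(concepts = concepts, source = file),
            class = "concept_registry")
}

#' @export
print.concept_registry <- function(x, ...) {
  cat("<concept_registry> ", length(x$concepts), " concepts\n", sep = "")
  invisible(x)
}

#' Tabulate a concept registry
#'
#' @param x A `concept_registry`.
#' @param ... Unused.
#' @return A tibble, one row per concept, for clinician review.
#' @export
as_tibble.concept_registry <- function(x, ...) {
  tibble(
    concept_id = vapply(x$concepts, `[[`, "", "concept_id"),
    label = vapply(x$concepts, `[[`, "", "label"),
    kind = vapply(x$concepts, `[[`, "", "kind"),
    resource_type = vapply(x$concepts, `[[`, "", "resource_type"),
    primary_code = vapply(x$concepts, function(cc) {
      paste0(cc$codings[[1]]$system, "|", cc$codings[[1]]$code)
    }, FUN.VALUE = ""),
    unit = vapply(x$concepts, function(cc) cc$unit %||% NA_character_,
                  FUN.VALUE = ""),
    value_type = vapply(x$concepts, `[[`, "", "value_type"),
    sources = vapply(x$concepts, function(cc) paste(cc$sources, collapse = ","),
                     FUN.VALUE = ""),
    inferred = vapply(x$concepts, `[[`, TRUE, "inferred")
  )
}

#' Resolve a concept id in a registry
#'
#' Lookup is case-sensitive; unknown ids raise an error naming the id and
#' its nearest matches.
#'
#' @param registry A `concept_registry`.
#' @param id Concept id token, e.g. `"SBP"`.
#' @return The `clinical_concept`.
#' @export
resolve_concept <- function(registry, id) {
  stopifnot(inherits(registry, "concept_registry"))
  cc <- registry$concepts[[id]]
  if (is.null(cc) || !identical(cc$concept_id, id)) {
    near <- names(registry$concepts)[
      tolower(names(registry$concepts)) == tolower(id)]
    hint <- if (length(near)) paste0(" (did you mean: ",
                                     paste(near, collapse = ", "), "?)") else ""
    cds_abort(paste0("unknown concept id '", id, "'", hint),
              "concept_not_found")
  }
  cc
}

#' Cross-check a registry against a knowledge base
#'
#' Verifies that every concept referenced by any rule condition or input
#' declaration exists in the registry (error level), and flags registry
#' concepts never referenced by a rule (warning level).
#'
#' @param registry A `concept_registry`.
#' @param kb A `cds_pack` (or its list of rules).
#' @return A tibble with columns `level`, `rule_id`, `concept`, `message`.
#' @export
check_registry_against_rules <- function(registry, kb) {
  rules <- if (inherits(kb, "cds_pack")) kb$rules else kb
  rows <- list()
  used <- character()
  for (rule in rules) {
    refs <- union(expression_concepts(rule$condition), rule$inputs)
    used <- union(used, refs)
    for (ref in refs) {
      if (is.null(registry$concepts[[ref]])) {
        rows[[length(rows) + 1L]] <- list(
          level = "error", rule_id = rule$rule_id, concept = ref,
          message = "concept referenced by rule is absent from registry"
        )
      }
    }
  }
  for (orphan in setdiff(names(registry$concepts), used)) {
    rows[[length(rows) + 1L]] <- list(
      level = "warning", rule_id = NA_character_, concept = orphan,
      message = "registry concept never referenced by any rule"
    )
  }
  tibble(
    level = vapply(rows, `[[`, "", "level"),
    rule_id = vapply(rows, `[[`, "", "rule_id"),
    concept = vapply(rows, `[[`, "", "concept"),
    message = vapply(rows, `[[`, "", "message")
  )
}
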