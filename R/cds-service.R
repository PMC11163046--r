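# CDS-Hooks service layer: discovery document, prefetch resolution against
# an in-process patient-bundle store, and service invocation. There is no
# network dependency: the request/response handlers consume and produce the
# CDS-Hooks JSON wire format directly, and a remote FHIR server adapter is
# an interface stub only.

PREFETCH_SEARCH_PARAMS <- c("patient", "code", "status", "_sort", "_count")

# "Observation?patient={{context.patientId}}&code=http://loinc.org|8480-6
#  &_sort=-date&_count=1" -> list(type, params)
parse_prefetch_template <- function(template) {
  parts <- strsplit(template, "?", fixed = TRUE)[[1]]
  type <- parts[1]
  params <- list()
  if (length(parts) > 1L && nzchar(parts[2])) {
    for (kv in strsplit(parts[2], "&", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) {
        cds_abort(paste0("malformed query parameter '", kv, "'"),
                  "prefetch_schema_error")
      }
      params[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    }
  }
  list(type = type, params = params)
}

validate_prefetch_template <- function(template, service_id = "?") {
  q <- parse_prefetch_template(template)
  if (!q$type %in% FHIR_RESOURCE_TYPES) {
    cds_abort(paste0("service '", service_id,
                     "': prefetch queries unsupported resource type '",
                     q$type, "'"),
              "prefetch_schema_error")
  }
  bad <- setdiff(names(q$params), PREFETCH_SEARCH_PARAMS)
  if (length(bad) > 0L) {
    cds_abort(paste0("service '", service_id,
                     "': unsupported search parameter(s): ",
                     paste(bad, collapse = ", ")),
              "prefetch_schema_error")
  }
  pat <- q$params$patient
  if (!is.null(pat) && !identical(pat, "{{context.patientId}}")) {
    cds_abort(paste0("service '", service_id,
                     "': prefetch may only reference {{context.patientId}}"),
              "prefetch_schema_error")
  }
  invisible(q)
}

# Emulated FHIR search over an in-process bundle; only what prefetch needs.
query_bundle <- function(bundle, template, patient_id) {
  q <- parse_prefetch_template(template)
  hits <- list()
  for (env in c(list(bundle$patient), bundle$resources)) {
    if (env$resource_type != q$type) next
    if (!is.null(q$params$patient)) {
      if (env$resource_type == "Patient") {
        if (!identical(env$id, patient_id)) next
      } else {
        ref <- env$attributes$subject$reference %||%
          env$attributes$patient$reference %||% ""
        if (!identical(ref, paste0("Patient/", patient_id))) next
      }
    }
    if (!is.null(q$params$status) &&
        !identical(env$attributes$status %||% "", q$params$status)) next
    if (!is.null(q$params$code)) {
      sc <- strsplit(q$params$code, "|", fixed = TRUE)[[1]]
      system <- if (length(sc) == 2L) sc[1] else ""
      code <- normalize_code(sc[length(sc)])
      if (!coding_matches(codings_of(env$attributes$code), system, code)) next
    }
    hits[[length(hits) + 1L]] <- env
  }
  sort_key <- q$params[["_sort"]]
  if (!is.null(sort_key)) {
    if (!sort_key %in% c("date", "-date")) {
      cds_abort(paste0("unsupported _sort value '", sort_key, "'"),
                "prefetch_schema_error")
    }
    keys <- vapply(hits, function(h) datetime_key(observation_effective(h)),
                   FUN.VALUE = "")
    ids <- vapply(hits, function(h) h$id %||% "", FUN.VALUE = "")
    hits <- hits[order(keys, ids, decreasing = startsWith(sort_key, "-"))]
  }
  n <- q$params[["_count"]]
  if (!is.null(n)) hits <- utils::head(hits, as.integer(n))
  hits
}

#' Resolve a service's prefetch templates against a patient bundle
#'
#' Each template is evaluated as an emulated FHIR search over the bundle
#' (parameters: `patient`, `code` as `system|code`, `status`, `_sort` by
#' date, `_count`). An empty result maps to an empty entry, not an error.
#'
#' @param descriptor A `service_descriptor`.
#' @param source A `fhir_bundle` serving as the patient data store.
#' @return Named list: prefetch name to list of matching resources (as FHIR
#'   JSON-style lists).
#' @export
resolve_prefetch <- function(descriptor, source) {
  stopifnot(inherits(descriptor, "service_descriptor"),
            inherits(source, "fhir_bundle"))
  out <- lapply(descriptor$prefetch, function(tpl) {
    lapply(query_bundle(source, tpl, source$patient$id),
           resource_to_json_list)
  })
  out
}

# Every concept a service's rules use must be retrievable through >= 1 of
# the service's prefetch templates: the template must target the concept's
# resource type and either carry no code filter or a code filter matching
# one of the concept's codings (the blood-pressure panel code also covers
# its component concepts).
BP_PANEL_CODE <- "85354-9"
BP_COMPONENT_CODES <- c("8480-6", "8482-4")

prefetch_covers_concept <- function(queries, concept) {
  for (q in queries) {
    if (q$type != concept$resource_type &&
        !(q$type %in% c("MedicationStatement", "MedicationRequest") &&
          concept$resource_type %in% c("MedicationStatement",
                                       "MedicationRequest"))) next
    codep <- q$params$code
    if (is.null(codep)) return(TRUE)
    sc <- strsplit(codep, "|", fixed = TRUE)[[1]]
    qcode <- normalize_code(sc[length(sc)])
    ccodes <- vapply(concept$codings, `[[`, "", "code")
    if (qcode %in% ccodes) return(TRUE)
    if (qcode == BP_PANEL_CODE && any(ccodes %in% BP_COMPONENT_CODES)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Check prefetch completeness for every service in a pack
#'
#' Startup-time validator proving that every rule input concept is reachable
#' through at least one prefetch entry of its service.
#'
#' @param pack A `cds_pack` (or the raw pieces before full construction).
#' @return A tibble of violations (`service_id`, `rule_id`, `concept`);
#'   zero rows when complete.
#' @export
check_prefetch_completeness <- function(pack) {
  rows <- list()
  for (svc in pack$services) {
    queries <- lapply(unlist(svc$prefetch), parse_prefetch_template)
    for (rid in svc$rule_ids) {
      rule <- pack$rules[[rid]]
      for (cid in union(rule$inputs, expression_concepts(rule$condition))) {
        cc <- pack$registry$concepts[[cid]]
        if (is.null(cc)) next # reported by the registry closure check
        if (!prefetch_covers_concept(queries, cc)) {
          rows[[length(rows) + 1L]] <- list(
            service_id = svc$service_id, rule_id = rid, concept = cid
          )
        }
      }
    }
  }
  tibble(
    service_id = vapply(rows, `[[`, "", "service_id"),
    rule_id = vapply(rows, `[[`, "", "rule_id"),
    concept = vapply(rows, `[[`, "", "concept")
  )
}

as_pack_list <- function(packs) {
  if (inherits(packs, "cds_pack")) packs <- list(packs)
  ids <- unlist(lapply(packs, function(p) names(p$services)))
  if (anyDuplicated(ids)) {
    cds_abort(paste0("duplicate service id(s) across packs: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "pack_schema_error")
  }
  packs
}

all_services <- function(packs) {
  svcs <- unlist(lapply(as_pack_list(packs), `[[`, "services"),
                 recursive = FALSE)
  svcs[order(vapply(svcs, `[[`, "", "service_id"))]
}

find_service <- function(packs, service_id) {
  for (pack in as_pack_list(packs)) {
    if (service_id %in% names(pack$services)) {
      return(list(pack = pack, service = pack$services[[service_id]]))
    }
  }
  cds_abort(paste0("unknown service '", service_id, "' (HTTP 404)"),
            "service_not_found")
}

#' CDS-Hooks discovery document
#'
#' @param packs A `cds_pack` or list of packs.
#' @return The discovery document as an R list (`list(services = ...)`),
#'   services in stable `service_id` order, ready for JSON serialization.
#' @export
discovery <- function(packs = list()) {
  services <- lapply(all_services(packs), function(svc) {
    out <- list(
      id = svc$service_id,
      hook = svc$hook,
      title = svc$title,
      description = svc$description
    )
    if (length(svc$prefetch) > 0L) out$prefetch <- svc$prefetch
    out
  })
  list(services = unname(services))
}

#' Construct a CDS-Hooks request object
#'
#' @param hook Hook id (e.g. `"patient-view"`).
#' @param patient_id Patient id within the data source.
#' @param prefetch Optional client-supplied prefetch (overrides server-side
#'   resolution per CDS-Hooks).
#' @param hook_instance Request uuid; generated when omitted.
#' @return A `cds_request`.
#' @export
cds_request <- function(hook = "patient-view", patient_id,
                        prefetch = NULL, hook_instance = NULL) {
  if (!nzchar(patient_id %||% "")) {
    cds_abort("patientId must be non-empty (HTTP 400)", "bad_request")
  }
  structure(
    list(hook = hook, hookInstance = hook_instance %||% new_uuid(),
         context = list(patientId = patient_id), prefetch = prefetch),
    class = "cds_request"
  )
}

#' Invoke a CDS service against a patient bundle
#'
#' For each rule attached to the service, the condition is evaluated with
#' three-valued logic; cards are rendered for rules evaluating `"true"`
#' (unknown suppresses the card), in rule declaration order, deduplicated
#' by card id.
#'
#' @param packs A `cds_pack` or list of packs.
#' @param service_id Service to invoke.
#' @param request A `cds_request`.
#' @param source A `fhir_bundle` patient data store.
#' @param now Injectable "today" used for date placeholders; defaults to
#'   the current date.
#' @param verbose If `TRUE`, log one line per rule evaluated.
#' @return CDS-Hooks response as an R list (`list(cards = ...)`).
#' @export
invoke <- function(packs, service_id, request, source, now = Sys.Date(),
                   verbose = FALSE) {
  render_response(
    invoke_rendered(packs, service_id, request, source, now, verbose)
  )
}

# Shared core of invoke()/invoke_all(): returns rendered_card objects, which
# still carry the internal card_id (the wire format does not).
invoke_rendered <- function(packs, service_id, request, source,
                            now = Sys.Date(), verbose = FALSE) {
  stopifnot(inherits(request, "cds_request"), inherits(source, "fhir_bundle"))
  hit <- find_service(packs, service_id)
  svc <- hit$service
  pack <- hit$pack
  if (!identical(request$hook, svc$hook)) {
    cds_abort(paste0("request hook '", request$hook,
                     "' does not match service hook '", svc$hook,
                     "' (HTTP 400)"),
              "bad_request")
  }
  if (!identical(request$context$patientId, source$patient$id)) {
    cds_abort("context.patientId does not resolve in the data source (HTTP 400)",
              "bad_request")
  }
  # client-supplied prefetch overrides server-side resolution
  eval_bundle <- if (!is.null(request$prefetch)) {
    prefetched <- unlist(unname(request$prefetch), recursive = FALSE)
    envs <- lapply(prefetched, function(res) {
      fhir_resource(res$resourceType, id = res$id,
                    attributes = res[setdiff(names(res),
                                             c("resourceType", "id"))])
    })
    fhir_bundle(source$patient,
                envs[vapply(envs, `[[`, "", "resource_type") != "Patient"])
  } else {
    source
  }
  bindings <- list(PatientId = source$patient$id)
  seen <- character()
  cards <- list()
  for (rule in pack$rules[svc$rule_ids]) {
    tv <- evaluate(rule$condition, eval_bundle, pack$registry, now)
    if (verbose) {
      message(sprintf("invoke %s: %s -> %s [%s]", service_id, rule$rule_id,
                      tv, paste(rule$card_ids, collapse = ",")))
    }
    if (!identical(tv, "true")) next
    for (cid in setdiff(rule$card_ids, seen)) {
      cards[[length(cards) + 1L]] <- render_card(pack$cards[[cid]], now,
                                                 bindings)
      seen <- c(seen, cid)
    }
  }
  cards
}

#' Invoke every service of a pack and collect the emitted cards
#'
#' Convenience wrapper used by scenario contract tests and the command-line
#' `evaluate` subcommand.
#'
#' @inheritParams invoke
#' @return A tibble with columns `service_id`, `card_id`, `summary`.
#' @export
invoke_all <- function(packs, source, now = Sys.Date()) {
  rows <- list()
  for (svc in all_services(packs)) {
    req <- cds_request(hook = svc$hook, patient_id = source$patient$id)
    cards <- invoke_rendered(packs, svc$service_id, req, source, now = now)
    for (card in cards) {
      rows[[length(rows) + 1L]] <- list(service_id = svc$service_id,
                                        card_id = card$card_id,
                                        summary = card$summary)
    }
  }
  tibble(
    service_id = vapply(rows, `[[`, "", "service_id"),
    card_id = vapply(rows, `[[`, "", "card_id"),
    summary = vapply(rows, `[[`, "", "summary")
  )
}
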