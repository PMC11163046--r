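# Content packs: the declarative knowledge base for one guideline section.
# A pack directory holds a pack manifest, a concept file, a rules file, one
# card-template document per card, and a services file. Loading is atomic:
# the first referential-closure violation fails the whole load.

GUIDELINE_SECTIONS <- c(
  "MD&MCI", "Physical exercise", "Nutrition & hydration",
  "Commonly used drugs", "Coronary artery disease", "Heart failure",
  "Hypertension", "Diabetes", "Chronic kidney disease", "COPD", "Stroke",
  "Sarcopenia & frailty", "Caregiver support"
)

PURPOSE_CATEGORIES <- c(
  "diagnosis", "lifestyle-advice", "goal-management", "drug-treatment",
  "adverse-events-contraindications", "information-guidance",
  "symptom-recording", "complication-referral", "planning-next-visit"
)

new_cds_rule <- function(rule_id, section, purpose_category, context = "",
                         trigger = "", inputs = character(),
                         condition, card_ids, source = "") {
  err <- function(msg) cds_abort(
    paste0("rule '", rule_id, "': ", msg), "pack_schema_error"
  )
  if (!grepl("^[A-Za-z][A-Za-z&  -]* \\d+$", rule_id)) {
    err("rule id must have the form '<Section> <n>'")
  }
  if (!section %in% GUIDELINE_SECTIONS) err("unknown guideline section")
  if (!purpose_category %in% PURPOSE_CATEGORIES) {
    err(paste0("unknown purpose category '", purpose_category, "'"))
  }
  if (length(card_ids) == 0L) err("at least one output card required")
  missing_inputs <- setdiff(expression_concepts(condition), inputs)
  if (length(missing_inputs) > 0L) {
    err(paste0("condition references concepts not declared as inputs: ",
               paste(missing_inputs, collapse = ", ")))
  }
  structure(
    list(rule_id = rule_id, section = section,
         purpose_category = purpose_category, context = context,
         trigger = trigger, inputs = inputs, condition = condition,
         card_ids = card_ids, source = source),
    class = "cds_rule"
  )
}

#' @export
print.cds_rule <- function(x, ...) {
  cat("<cds_rule> ", x$rule_id, " (", x$purpose_category, ")\n  ",
      format(x$condition), " -> ", paste(x$card_ids, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

new_service_descriptor <- function(service_id, hook = "patient-view",
                                   title = "", description = "",
                                   prefetch = list(),
                                   rule_ids = character()) {
  if (!grepl("^[a-z0-9][a-z0-9-]*$", service_id)) {
    cds_abort(paste0("invalid service id '", service_id, "'"),
              "pack_schema_error")
  }
  if (length(rule_ids) == 0L) {
    cds_abort(paste0("service '", service_id, "' has no attached rules"),
              "pack_schema_error")
  }
  for (tpl in unlist(prefetch)) {
    validate_prefetch_template(tpl, service_id)
  }
  structure(
    list(service_id = service_id, hook = hook, title = title,
         description = description, prefetch = prefetch,
         rule_ids = rule_ids),
    class = "service_descriptor"
  )
}

#' Load a content pack from a directory
#'
#' Loads and cross-validates the concept registry, rules, card templates and
#' service descriptors of one guideline section. The load fails atomically
#' on the first closure violation (dangling card id, dangling concept,
#' duplicate rule id, rule attached to no service, incomplete prefetch).
#'
#' @param dir Path to a content-pack directory.
#' @return A `cds_pack`.
#' @export
load_pack <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      cds_abort(paste0("content pack is missing ", f), "pack_schema_error")
    }
    p
  }
  manifest <- yaml::read_yaml(need("pack.yaml"))
  registry <- load_concept_table(need("concepts.yaml"))
  rules_doc <- yaml::read_yaml(need("rules.yaml"))
  card_files <- sort(list.files(file.path(dir, "cards"),
                                pattern = "\\.yaml$", full.names = TRUE))
  if (length(card_files) == 0L) {
    cds_abort("content pack has no card templates", "pack_schema_error")
  }
  cards <- lapply(card_files, card_template_from_yaml)
  names(cards) <- vapply(cards, `[[`, "", "card_id")
  if (anyDuplicated(names(cards))) {
    cds_abort("duplicate card ids in pack", "pack_schema_error")
  }

  rules <- lapply(rules_doc$rules, function(r) {
    condition <- parse_expression(r$condition)
    new_cds_rule(
      rule_id = r$id, section = r$section %||% manifest$section,
      purpose_category = r$purpose, context = r$context %||% "",
      trigger = r$trigger %||% "", inputs = unlist(r$inputs %||% character()),
      condition = condition, card_ids = unlist(r$cards),
      source = r$source %||% ""
    )
  })
  rule_ids <- vapply(rules, `[[`, "", "rule_id")
  if (anyDuplicated(rule_ids)) {
    cds_abort(paste0("duplicate rule id(s): ",
                     paste(unique(rule_ids[duplicated(rule_ids)]),
                           collapse = ", ")),
              "pack_schema_error")
  }
  names(rules) <- rule_ids

  # referential closure: rules -> concepts, rules -> cards
  for (rule in rules) {
    validate_expression(rule$condition, registry)
    for (cid in rule$inputs) resolve_concept(registry, cid)
    dangling <- setdiff(rule$card_ids, names(cards))
    if (length(dangling) > 0L) {
      cds_abort(paste0("rule '", rule$rule_id, "' cites unknown card(s): ",
                       paste(dangling, collapse = ", ")),
                "pack_schema_error")
    }
  }

  services_doc <- yaml::read_yaml(need("services.yaml"))
  services <- lapply(services_doc$services, function(s) {
    svc <- new_service_descriptor(
      service_id = s$id, hook = s$hook %||% "patient-view",
      title = s$title %||% s$id, description = s$description %||% "",
      prefetch = s$prefetch %||% list(), rule_ids = unlist(s$rules)
    )
    dangling <- setdiff(svc$rule_ids, rule_ids)
    if (length(dangling) > 0L) {
      cds_abort(paste0("service '", svc$service_id,
                       "' cites unknown rule(s): ",
                       paste(dangling, collapse = ", ")),
                "pack_schema_error")
    }
    svc
  })
  names(services) <- vapply(services, `[[`, "", "service_id")
  if (anyDuplicated(names(services))) {
    cds_abort("duplicate service ids in pack", "pack_schema_error")
  }
  orphaned <- setdiff(rule_ids, unlist(lapply(services, `[[`, "rule_ids")))
  if (length(orphaned) > 0L) {
    cds_abort(paste0("rule(s) attached to no service: ",
                     paste(orphaned, collapse = ", ")),
              "pack_schema_error")
  }

  pack <- structure(
    list(name = manifest$name, version = manifest$version %||% "0.0.0",
         section = manifest$section, metadata = manifest$metadata %||% list(),
         registry = registry, rules = rules, cards = cards,
         services = services),
    class = "cds_pack"
  )
  reg_check <- check_registry_against_rules(registry, pack)
  if (any(reg_check$level == "error")) {
    bad <- reg_check[reg_check$level == "error", ]
    cds_abort(paste0("registry closure violations: ",
                     paste0(bad$rule_id, " -> ", bad$concept, collapse = "; ")),
              "pack_schema_error")
  }
  pf <- check_prefetch_completeness(pack)
  if (nrow(pf) > 0L) {
    cds_abort(paste0("prefetch completeness violations: ",
                     paste0(pf$service_id, ": ", pf$concept, collapse = "; ")),
              "pack_schema_error")
  }
  pack
}

#' @export
print.cds_pack <- function(x, ...) {
  cat("<cds_pack> ", x$name, " v", x$version, ": ",
      length(x$registry$concepts), " concepts, ", length(x$rules),
      " rules, ", length(x$cards), " cards, ", length(x$services),
      " services\n", sep = "")
  invisible(x)
}

#' Rules attached to a service, in declaration order
#'
#' @param pack A `cds_pack`.
#' @param service_id A service id present in the pack.
#' @return List of `cds_rule` objects, stable across loads.
#' @export
rules_for_service <- function(pack, service_id) {
  stopifnot(inherits(pack, "cds_pack"))
  svc <- pack$services[[service_id]]
  if (is.null(svc)) {
    cds_abort(paste0("unknown service id '", service_id, "'"),
              "service_not_found")
  }
  pack$rules[svc$rule_ids]
}

#' Traceability report for a content pack
#'
#' One row per rule, carrying the guideline chapter/page citation verbatim
#' so stakeholders can track every rule back to its source.
#'
#' @param pack A `cds_pack`.
#' @param file Optional path; when given, the report is also written as
#'   tab-separated text.
#' @return A tibble with columns `rule_id`, `purpose_category`, `source`,
#'   `card_ids`, `concepts`.
#' @export
traceability_report <- function(pack, file = NULL) {
  stopifnot(inherits(pack, "cds_pack"))
  out <- tibble(
    rule_id = vapply(pack$rules, `[[`, "", "rule_id"),
    purpose_category = vapply(pack$rules, `[[`, "", "purpose_category"),
    source = vapply(pack$rules, function(r) {
      if (nzchar(r$source)) r$source else
        paste(unique(vapply(pack$cards[r$card_ids], function(cd) {
          cd$source$citation %||% ""
        }, FUN.VALUE = "")), collapse = "; ")
    }, FUN.VALUE = ""),
    card_ids = vapply(pack$rules, function(r) paste(r$card_ids, collapse = ", "),
                      FUN.VALUE = ""),
    concepts = vapply(pack$rules, function(r) paste(r$inputs, collapse = ", "),
                      FUN.VALUE = "")
  )
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
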