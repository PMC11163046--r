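# CDS-Hooks card templates and rendering. A template mirrors the
# specification tables field for field: summary, detail, source, indicator
# and (for suggestion cards) suggestions whose actions embed parametrized
# FHIR resources. Rendering resolves {{Today [+ N unit]}} date placeholders
# and named bindings, validates every embedded resource, and never mutates
# the template.

CARD_INDICATORS <- c("info", "warning", "critical")
ACTION_TYPES <- c("create", "delete", "update")
ACTION_KINDS <- c("lab-order", "referral", "appointment", "patient-activity",
                  "education-material", "goal", "medication", "autofill")

# Fixed mapping from the seven guideline action kinds (plus autofill) to the
# FHIR resource type each one embeds.
ACTION_KIND_RESOURCE <- c(
  `lab-order` = "ServiceRequest",
  referral = "ServiceRequest",
  `patient-activity` = "ServiceRequest",
  appointment = "Appointment",
  `education-material` = "CommunicationRequest",
  goal = "Goal",
  medication = "MedicationRequest",
  autofill = "Condition"
)

new_card_template <- function(card_id, summary, detail = NULL, source,
                              indicator = "info", suggestions = list(),
                              selection_behavior = NULL, inferred = FALSE) {
  err <- function(msg) cds_abort(
    paste0("card '", card_id, "': ", msg), "card_schema_error"
  )
  if (!nzchar(summary %||% "")) err("summary must be non-empty")
  if (nchar(summary) > 140) err("summary must be at most 140 characters")
  if (!nzchar(source$citation %||% "")) err("source citation must be non-empty")
  if (!indicator %in% CARD_INDICATORS) err("unknown indicator")
  if (length(suggestions) > 1L && is.null(selection_behavior)) {
    err("selection_behavior required when a card has multiple suggestions")
  }
  if (length(suggestions) <= 1L && !is.null(selection_behavior)) {
    err("selection_behavior only allowed with multiple suggestions")
  }
  for (sg in suggestions) {
    if (!nzchar(sg$label %||% "")) err("every suggestion needs a label")
    if (length(sg$actions) == 0L) err("every suggestion needs >= 1 action")
    for (ac in sg$actions) {
      if (!(ac$type %||% "") %in% ACTION_TYPES) err("unknown action type")
      if (!(ac$kind %||% "") %in% ACTION_KINDS) err("unknown action kind")
      rt <- ac$resource$resourceType %||% ""
      if (!identical(rt, unname(ACTION_KIND_RESOURCE[[ac$kind]]))) {
        err(paste0("action kind '", ac$kind, "' must embed a ",
                   ACTION_KIND_RESOURCE[[ac$kind]], ", found '", rt, "'"))
      }
    }
  }
  structure(
    list(card_id = card_id, summary = summary, detail = detail,
         source = source, indicator = indicator, suggestions = suggestions,
         selection_behavior = selection_behavior, inferred = isTRUE(inferred)),
    class = "card_template"
  )
}

#' @export
print.card_template <- function(x, ...) {
  cat("<card_template> ", x$card_id, " [", x$indicator, "] ",
      if (length(x$suggestions) == 0L) "information card" else
        paste0(length(x$suggestions), " suggestion(s)"),
      "\n  ", x$summary, "\n", sep = "")
  invisible(x)
}

#' Is a card an information card (no suggestions)?
#' @param tpl A `card_template` or `rendered_card`.
#' @return Logical.
#' @export
is_information_card <- function(tpl) length(tpl$suggestions) == 0L

card_template_from_yaml <- function(file) {
  x <- yaml::read_yaml(file)
  # resources in card files are plain attribute maps; codes normalize on load
  suggestions <- lapply(x$suggestions %||% list(), function(sg) {
    list(label = sg$label, actions = lapply(sg$actions, function(ac) {
      list(type = ac$type, description = ac$description, kind = ac$kind,
           resource = normalize_resource_codes(ac$resource))
    }))
  })
  new_card_template(
    card_id = x$card_id, summary = x$summary, detail = x$detail,
    source = x$source, indicator = x$indicator %||% "info",
    suggestions = suggestions,
    selection_behavior = x$selection_behavior,
    inferred = isTRUE(x$inferred)
  )
}

# --- placeholders ---------------------------------------------------------

PLACEHOLDER_RE <- "\\{\\{[^}]*\\}\\}"

#' Resolve a card-template placeholder token
#'
#' Grammar: `{{Today}}`, `{{Today + N days|weeks|months}}` or
#' `{{<binding-name>}}`. Calendar arithmetic is proleptic Gregorian; month
#' addition clamps to month end (`{{Today + 1 month}}` from 2024-01-31 gives
#' 2024-02-29).
#'
#' @param token The placeholder, braces included.
#' @param now A `Date` (or ISO date string) standing for "today".
#' @param bindings Named list of values for non-date placeholders.
#' @return The concrete value as a string.
#' @export
resolve_placeholder <- function(token, now, bindings = list()) {
  now <- as.Date(now)
  inner <- trimws(sub("^\\{\\{(.*)\\}\\}$", "\\1", token))
  if (!grepl("^\\{\\{[^}]*\\}\\}$", token)) {
    cds_abort(paste0("malformed placeholder token: '", token, "'"),
              "placeholder_error")
  }
  m <- regmatches(
    inner,
    regexec("^Today(\\s*\\+\\s*(\\d+)\\s*(day|days|week|weeks|month|months))?$",
            inner)
  )[[1]]
  if (length(m) > 0) {
    if (!nzchar(m[2])) return(format(now, "%Y-%m-%d"))
    n <- as.integer(m[3])
    unit <- m[4]
    out <- switch(sub("s$", "", unit),
      day = now + n,
      week = now + 7L * n,
      # month arithmetic clamps to month end (Jan 31 + 1 month -> Feb 29/28)
      month = lubridate::add_with_rollback(now, lubridate::period(month = n))
    )
    return(format(out, "%Y-%m-%d"))
  }
  if (grepl("^[A-Za-z][A-Za-z0-9_.]*$", inner)) {
    if (!inner %in% names(bindings)) {
      cds_abort(paste0("unknown binding name in placeholder: '", inner, "'"),
                "placeholder_error")
    }
    return(as.character(bindings[[inner]]))
  }
  cds_abort(paste0("malformed placeholder token: '", token, "'"),
            "placeholder_error")
}

resolve_deep_impl <- function(x, now, bindings) {
  if (is.character(x) && length(x) == 1L) {
    tokens <- regmatches(x, gregexpr(PLACEHOLDER_RE, x))[[1]]
    for (tok in unique(tokens)) {
      x <- gsub(tok, resolve_placeholder(tok, now, bindings), x, fixed = TRUE)
    }
    return(x)
  }
  if (is.list(x)) return(lapply(x, resolve_deep_impl,
                                now = now, bindings = bindings))
  x
}

# --- rendering ------------------------------------------------------------

#' Render a card template into a concrete card
#'
#' Resolves all placeholders against `now` and `bindings`, validates every
#' embedded FHIR resource, and attaches a fresh uuid. The template is never
#' mutated and can be reused across patients.
#'
#' @param tpl A `card_template`.
#' @param now A `Date` used for `{{Today ...}}` arithmetic.
#' @param bindings Named list for non-date placeholders.
#' @return A `rendered_card`.
#' @export
render_card <- function(tpl, now = Sys.Date(), bindings = list()) {
  stopifnot(inherits(tpl, "card_template"))
  # placeholder failures are reported with the offending card's id
  resolve_placeholders_deep <- function(x, now, bindings) {
    withCallingHandlers(
      resolve_deep_impl(x, now, bindings),
      placeholder_error = function(e) {
        cds_abort(paste0("card '", tpl$card_id, "': ", conditionMessage(e)),
                  "placeholder_error")
      }
    )
  }
  suggestions <- lapply(tpl$suggestions, function(sg) {
    actions <- lapply(sg$actions, function(ac) {
      res <- resolve_placeholders_deep(ac$resource, now, bindings)
      leftover <- unlist(lapply(rapply(res, identity, how = "unlist"),
                                function(s) grepl("\\{\\{", s)))
      if (any(leftover)) {
        cds_abort(paste0("card '", tpl$card_id,
                         "': unresolved placeholder in embedded resource"),
                  "placeholder_error")
      }
      env <- fhir_resource(res$resourceType,
                           id = res$id,
                           attributes = res[setdiff(names(res),
                                                    c("resourceType", "id"))])
      viol <- validate_resource(env)
      if (nrow(viol) > 0L) {
        cds_abort(paste0("card '", tpl$card_id, "': embedded ",
                         res$resourceType, " invalid: ",
                         paste0(viol$path, ": ", viol$message, collapse = "; ")),
                  "card_render_error")
      }
      list(type = ac$type,
           description = resolve_placeholders_deep(ac$description, now, bindings),
           kind = ac$kind,
           resource = res)
    })
    list(label = resolve_placeholders_deep(sg$label, now, bindings),
         uuid = new_uuid(), actions = actions)
  })
  structure(
    list(uuid = new_uuid(), card_id = tpl$card_id,
         summary = resolve_placeholders_deep(tpl$summary, now, bindings),
         detail = if (!is.null(tpl$detail))
           resolve_placeholders_deep(tpl$detail, now, bindings),
         source = tpl$source, indicator = tpl$indicator,
         suggestions = suggestions,
         selection_behavior = tpl$selection_behavior),
    class = "rendered_card"
  )
}

#' @export
print.rendered_card <- function(x, ...) {
  cat("<rendered_card> ", x$card_id, " [", x$indicator, "]\n  ",
      x$summary, "\n", sep = "")
  invisible(x)
}

rendered_card_to_list <- function(card) {
  out <- list(
    uuid = card$uuid,
    summary = card$summary,
    indicator = card$indicator,
    source = list(label = card$source$label %||% "Care guideline")
  )
  if (!is.null(card$source$url)) out$source$url <- card$source$url
  if (!is.null(card$detail)) out$detail <- card$detail
  if (length(card$suggestions) > 0L) {
    out$suggestions <- lapply(card$suggestions, function(sg) {
      list(label = sg$label, uuid = sg$uuid,
           actions = lapply(sg$actions, function(ac) {
             list(type = ac$type, description = ac$description,
                  resource = ac$resource)
           }))
    })
    if (!is.null(card$selection_behavior)) {
      out$selectionBehavior <- card$selection_behavior
    }
  }
  out
}

#' Assemble a CDS-Hooks response document from rendered cards
#'
#' Information cards are emitted without a `suggestions` key, per the
#' CDS-Hooks contract; card order follows the input order.
#'
#' @param cards List of `rendered_card` objects (may be empty).
#' @param as_json If `TRUE`, return JSON text instead of an R structure.
#' @return A list `list(cards = ...)` ready for JSON serialization, or JSON.
#' @export
render_response <- function(cards, as_json = FALSE) {
  doc <- list(cards = lapply(cards, rendered_card_to_list))
  if (as_json) {
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE, null = "null")))
  }
  doc
}
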