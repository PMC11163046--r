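# Rule condition expressions: a closed AST (comparisons, record presence,
# diagnosis/medication membership, workflow flags, boolean composition)
# evaluated over a patient bundle with Kleene three-valued logic. A missing
# measurement makes a comparison "unknown"; cards fire only on "true", so
# unknown suppresses guidance rather than guessing.

COMPARE_OPS <- c("<", "<=", ">", ">=", "==", "!=")

new_expr <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "cds_expr")
}

#' Condition-expression constructors
#'
#' Build the closed expression AST used in rule conditions: quantity/coded
#' comparisons over the latest value of a concept, presence tests, active
#' diagnosis and medication-class membership, workflow flags, and Kleene
#' boolean composition.
#'
#' @param concept A concept id registered in the pack's concept registry.
#' @param op One of `<`, `<=`, `>`, `>=`, `==`, `!=`.
#' @param value Numeric literal (quantity concepts), code string (coded
#'   concepts) or logical (boolean concepts).
#' @param unit Optional UCUM unit of the literal; must equal the concept
#'   unit when given.
#' @param atc_prefix An ATC code prefix, e.g. `"C07"` for beta blockers.
#' @param flag Concept id of a boolean workflow-state assessment.
#' @param is Logical the flag is compared against.
#' @param ...,x Child expressions.
#' @return A `cds_expr` AST node.
#' @name condition-expressions
NULL

#' @rdname condition-expressions
#' @export
expr_compare <- function(concept, op, value, unit = NULL) {
  stopifnot(op %in% COMPARE_OPS)
  new_expr("compare", concept = concept, op = op, value = value, unit = unit)
}

#' @rdname condition-expressions
#' @export
expr_exists <- function(concept) new_expr("exists", concept = concept)

#' @rdname condition-expressions
#' @export
expr_has_diagnosis <- function(concept) new_expr("diagnosis", concept = concept)

#' @rdname condition-expressions
#' @export
expr_on_medication <- function(atc_prefix) {
  stopifnot(nzchar(atc_prefix), grepl("^[A-Z0-9]+$", atc_prefix))
  new_expr("medication", atc_prefix = atc_prefix)
}

#' @rdname condition-expressions
#' @export
expr_flag <- function(flag, is = TRUE) {
  new_expr("flag", flag = flag, is = isTRUE(is))
}

#' @rdname condition-expressions
#' @export
expr_and <- function(...) new_expr("and", children = list(...))

#' @rdname condition-expressions
#' @export
expr_or <- function(...) new_expr("or", children = list(...))

#' @rdname condition-expressions
#' @export
expr_not <- function(x) new_expr("not", children = list(x))

# Parse the structured YAML form used in rule files into the AST.
# Node shapes: {all: [...]}, {any: [...]}, {not: ...},
# {concept:, op:, value:, unit:}, {exists:}, {diagnosis:},
# {medication: prefix}, {flag:, is:}.
parse_expression <- function(x) {
  stopifnot(is.list(x))
  nm <- names(x)
  if ("all" %in% nm) {
    do.call(expr_and, lapply(x$all, parse_expression))
  } else if ("any" %in% nm) {
    do.call(expr_or, lapply(x$any, parse_expression))
  } else if ("not" %in% nm) {
    expr_not(parse_expression(x$not))
  } else if ("concept" %in% nm) {
    expr_compare(x$concept, x$op, x$value, x$unit)
  } else if ("exists" %in% nm) {
    expr_exists(x$exists)
  } else if ("diagnosis" %in% nm) {
    expr_has_diagnosis(x$diagnosis)
  } else if ("medication" %in% nm) {
    expr_on_medication(x$medication)
  } else if ("flag" %in% nm) {
    expr_flag(x$flag, x$is %||% TRUE)
  } else {
    cds_abort(paste0("unrecognized expression node: {",
                     paste(nm, collapse = ", "), "}"),
              "expression_schema_error")
  }
}

# All concept ids an expression references (flags are boolean concepts too).
expression_concepts <- function(expr) {
  stopifnot(inherits(expr, "cds_expr"))
  switch(expr$kind,
    compare = ,
    exists = ,
    diagnosis = expr$concept,
    flag = expr$flag,
    medication = character(),
    and = ,
    or = ,
    not = unique(unlist(lapply(expr$children, expression_concepts))),
    character()
  )
}

# Validate leaves against the registry; raised at load time, not evaluation.
validate_expression <- function(expr, registry) {
  switch(expr$kind,
    compare = {
      cc <- resolve_concept(registry, expr$concept)
      if (cc$value_type == "quantity") {
        if (!is.numeric(expr$value)) {
          cds_abort(paste0("comparison on quantity concept '", expr$concept,
                           "' needs a numeric literal"),
                    "expression_schema_error")
        }
        if (!is.null(expr$unit) && !identical(expr$unit, cc$unit)) {
          cds_abort(paste0("literal unit '", expr$unit,
                           "' does not match concept unit '", cc$unit,
                           "' for '", expr$concept, "'"),
                    "expression_schema_error")
        }
      }
    },
    exists = ,
    diagnosis = invisible(resolve_concept(registry, expr$concept)),
    flag = {
      cc <- resolve_concept(registry, expr$flag)
      if (cc$value_type != "boolean") {
        cds_abort(paste0("flag '", expr$flag,
                         "' must be a boolean assessment concept"),
                  "expression_schema_error")
      }
    },
    medication = invisible(NULL),
    and = ,
    or = ,
    not = lapply(expr$children, validate_expression, registry = registry)
  )
  invisible(expr)
}

#' Compact text rendering of a condition expression
#'
#' @param x A `cds_expr`.
#' @param ... Unused.
#' @return A single string, e.g. `"[SBP] >= 140 OR [DBP] >= 90"`.
#' @export
format.cds_expr <- function(x, ...) {
  switch(x$kind,
    compare = paste0("[", x$concept, "] ", x$op, " ", x$value,
                     if (!is.null(x$unit)) paste0(" ", x$unit)),
    exists = paste0("EXISTS [", x$concept, "]"),
    diagnosis = paste0("HAS-DIAGNOSIS [", x$concept, "]"),
    medication = paste0("ON-MEDICATION ", x$atc_prefix, "*"),
    flag = paste0("[", x$flag, "] IS ", if (x$is) "TRUE" else "FALSE"),
    and = paste0("(", paste(vapply(x$children, format, ""), collapse = " AND "), ")"),
    or = paste0("(", paste(vapply(x$children, format, ""), collapse = " OR "), ")"),
    not = paste0("NOT ", format(x$children[[1]]))
  )
}

#' @export
print.cds_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# --- value selection over a bundle --------------------------------------

observation_effective <- function(env) {
  env$attributes$effectiveDateTime %||%
    env$attributes$effectivePeriod$start %||%
    env$attributes$issued %||% ""
}

# Extract (value, unit) for a concept from a matching resource, looking into
# blood-pressure-panel components when the concept code sits in a component.
extract_concept_value <- function(env, concept) {
  code_match <- function(codeable) {
    any(vapply(concept$codings, function(cd) {
      coding_matches(codings_of(codeable), cd$system, cd$code)
    }, FUN.VALUE = TRUE))
  }
  node <- NULL
  if (code_match(env$attributes$code)) {
    node <- env$attributes
  } else {
    for (comp in env$attributes$component %||% list()) {
      if (code_match(comp$code)) {
        node <- comp
        break
      }
    }
  }
  if (is.null(node)) return(NULL)
  if (!is.null(node$valueQuantity)) {
    list(value = node$valueQuantity$value, unit = node$valueQuantity$unit,
         type = "quantity")
  } else if (!is.null(node$valueBoolean)) {
    list(value = node$valueBoolean, unit = NULL, type = "boolean")
  } else if (!is.null(node$valueCodeableConcept)) {
    cd <- codings_of(node$valueCodeableConcept)
    list(value = if (length(cd)) cd[[1]]$code else NULL, unit = NULL,
         type = "coded")
  } else {
    list(value = NULL, unit = NULL, type = "none")
  }
}

#' Select the latest value of a concept in a bundle
#'
#' Among bundle resources matching the concept's resource type and any of
#' its codings (including blood-pressure panel components), returns the one
#' with the maximal effective time; ties are broken by the lexicographically
#' greater resource id. Raises an error when the matched observation's unit
#' differs from the concept unit (no implicit conversion).
#'
#' @param bundle A `fhir_bundle`.
#' @param concept A `clinical_concept`.
#' @param now Optional reference time used with per-concept maximum-age
#'   overrides (`max_age_days`); `NULL` disables the lookback window.
#' @return `NULL` when no match; otherwise a list with `value`, `unit`,
#'   `effective`, `resource_id`.
#' @export
select_latest <- function(bundle, concept, now = NULL) {
  stopifnot(inherits(bundle, "fhir_bundle"),
            inherits(concept, "clinical_concept"))
  hits <- list()
  for (env in bundle$resources) {
    if (env$resource_type != concept$resource_type) next
    val <- extract_concept_value(env, concept)
    if (is.null(val)) next
    eff <- observation_effective(env)
    if (!is.null(concept$max_age_days) && !is.null(now) && nzchar(eff)) {
      age <- as.numeric(difftime(as.Date(substr(datetime_key(eff), 1, 10)),
                                 as.Date(now), units = "days"))
      if (-age > concept$max_age_days) next
    }
    hits[[length(hits) + 1L]] <- list(env = env, val = val, eff = eff)
  }
  if (length(hits) == 0L) return(NULL)
  keys <- vapply(hits, function(h) datetime_key(h$eff), FUN.VALUE = "")
  ids <- vapply(hits, function(h) h$env$id %||% "", FUN.VALUE = "")
  best <- order(keys, ids, decreasing = TRUE)[1]
  h <- hits[[best]]
  if (!is.null(concept$unit) && !is.null(h$val$unit) &&
      !identical(h$val$unit, concept$unit)) {
    cds_abort(
      paste0("unit mismatch for concept '", concept$concept_id, "': observed '",
             h$val$unit, "', expected '", concept$unit,
             "' (no implicit conversion)"),
      "unit_mismatch_error"
    )
  }
  list(value = h$val$value, unit = h$val$unit, effective = h$eff,
       resource_id = h$env$id)
}

#' Active medications matching an ATC class prefix
#'
#' @param bundle A `fhir_bundle`.
#' @param atc_prefix Non-empty uppercase alphanumeric ATC prefix
#'   (e.g. `"C07"`); matching is on canonical ATC strings.
#' @return List of matching MedicationStatement/MedicationRequest envelopes
#'   with status `active` or `intended`; inactive records are excluded.
#' @export
active_medications <- function(bundle, atc_prefix) {
  stopifnot(nzchar(atc_prefix), grepl("^[A-Z0-9]+$", atc_prefix))
  keep <- list()
  for (env in bundle$resources) {
    if (!env$resource_type %in% c("MedicationStatement", "MedicationRequest")) next
    if (!(env$attributes$status %||% "") %in% c("active", "intended")) next
    codings <- codings_of(env$attributes$medicationCodeableConcept)
    atc <- vapply(codings, function(cd) {
      if (identical(cd$system %||% "", SYSTEM_URIS[["ATC"]]))
        normalize_code(cd$code %||% "") else ""
    }, FUN.VALUE = "")
    if (any(startsWith(atc, atc_prefix) & nzchar(atc))) {
      keep[[length(keep) + 1L]] <- env
    }
  }
  keep
}

# --- evaluation -----------------------------------------------------------

tv_chr <- function(x) {
  if (is.na(x)) "unknown" else if (x) "true" else "false"
}

compare_values <- function(op, lhs, rhs) {
  switch(op,
    "<" = lhs < rhs, "<=" = lhs <= rhs, ">" = lhs > rhs, ">=" = lhs >= rhs,
    "==" = identical_value(lhs, rhs), "!=" = !identical_value(lhs, rhs)
  )
}

identical_value <- function(lhs, rhs) {
  if (is.numeric(lhs) && is.numeric(rhs)) return(lhs == rhs)
  identical(as.character(lhs), as.character(rhs))
}

eval_expr <- function(expr, bundle, registry, now) {
  switch(expr$kind,
    compare = {
      cc <- resolve_concept(registry, expr$concept)
      m <- select_latest(bundle, cc, now = now)
      if (is.null(m) || is.null(m$value)) return(NA)
      compare_values(expr$op, m$value, expr$value)
    },
    exists = {
      cc <- resolve_concept(registry, expr$concept)
      !is.null(select_latest(bundle, cc, now = now))
    },
    diagnosis = {
      cc <- resolve_concept(registry, expr$concept)
      has_active_condition(bundle, cc)
    },
    medication = length(active_medications(bundle, expr$atc_prefix)) > 0L,
    flag = {
      cc <- resolve_concept(registry, expr$flag)
      m <- select_latest(bundle, cc, now = now)
      # a never-recorded workflow flag counts as FALSE, not unknown
      v <- if (is.null(m) || is.null(m$value)) FALSE else isTRUE(m$value)
      v == expr$is
    },
    and = Reduce(`&`, lapply(expr$children, eval_expr, bundle = bundle,
                             registry = registry, now = now)),
    or = Reduce(`|`, lapply(expr$children, eval_expr, bundle = bundle,
                            registry = registry, now = now)),
    not = !eval_expr(expr$children[[1]], bundle, registry, now)
  )
}

# A Condition is active unless its clinicalStatus says otherwise.
has_active_condition <- function(bundle, concept) {
  for (env in bundle$resources) {
    if (env$resource_type != "Condition") next
    match <- any(vapply(concept$codings, function(cd) {
      coding_matches(codings_of(env$attributes$code), cd$system, cd$code)
    }, FUN.VALUE = TRUE))
    if (!match) next
    status <- codings_of(env$attributes$clinicalStatus)
    code <- if (length(status)) status[[1]]$code else "active"
    if (code %in% c("active", "recurrence", "relapse")) return(TRUE)
  }
  FALSE
}

#' Evaluate a condition expression over a patient bundle
#'
#' Leaf comparisons on absent data evaluate to `"unknown"`; leaves are
#' combined with Kleene three-valued logic (`unknown OR true = true`,
#' `unknown AND false = false`, `NOT unknown = unknown`). Evaluation is
#' pure: identical inputs give identical results.
#'
#' @param expr A `cds_expr` (validated against the registry at load time).
#' @param bundle A `fhir_bundle`.
#' @param registry A `concept_registry`.
#' @param now Reference date/time (used by lookback windows).
#' @return One of `"true"`, `"false"`, `"unknown"`.
#' @export
evaluate <- function(expr, bundle, registry, now = Sys.Date()) {
  stopifnot(inherits(expr, "cds_expr"))
  tv_chr(eval_expr(expr, bundle, registry, now))
}
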