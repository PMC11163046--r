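# Minimal JSON-Schema (draft-07 subset) checker used for CDS-Hooks
# conformance tests. Supports: type, required, properties, items, enum,
# minLength, minItems, additionalProperties (boolean), $ref into
# "definitions". Values are R structures as produced by
# jsonlite::fromJSON(simplifyVector = FALSE).

#' Validate a JSON-like structure against a bundled JSON schema
#'
#' A deliberately small JSON-Schema subset checker used to assert that
#' discovery documents and card responses conform to the CDS-Hooks wire
#' format. Violations are returned, not raised, so callers can assert on
#' an empty result.
#'
#' @param x An R structure as returned by
#'   `jsonlite::fromJSON(simplifyVector = FALSE)`.
#' @param schema A schema, either a parsed list or a path to a schema file.
#' @return A tibble with columns `path` and `message`; zero rows means valid.
#' @export
validate_json_schema <- function(x, schema) {
  if (is.character(schema) && length(schema) == 1L) {
    schema <- jsonlite::fromJSON(schema, simplifyVector = FALSE)
  }
  out <- schema_check(x, schema, path = "$", root = schema)
  tibble(
    path = vapply(out, `[[`, "", "path"),
    message = vapply(out, `[[`, "", "message")
  )
}

#' Path to a bundled CDS-Hooks JSON schema
#'
#' @param which `"response"` (card response) or `"discovery"`.
#' @return File path inside the installed package.
#' @export
cds_hooks_schema <- function(which = c("response", "discovery")) {
  which <- match.arg(which)
  system.file("schemas", paste0("cds-hooks-", which, ".schema.json"),
              package = "cdscards", mustWork = TRUE)
}

schema_violation <- function(path, message) {
  list(list(path = path, message = message))
}

schema_type_of <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) "object" else "array"
  } else if (is.logical(x)) {
    "boolean"
  } else if (is.numeric(x)) {
    if (is.integer(x) || isTRUE(all.equal(x, round(x)))) "integer" else "number"
  } else if (is.character(x)) {
    "string"
  } else {
    "unknown"
  }
}

schema_check <- function(x, schema, path, root) {
  if (!is.null(schema[["$ref"]])) {
    ref <- sub("^#/definitions/", "", schema[["$ref"]])
    schema <- root$definitions[[ref]]
    if (is.null(schema)) {
      return(schema_violation(path, paste0("unresolvable $ref ", ref)))
    }
  }
  out <- list()
  typ <- schema_type_of(x)
  if (!is.null(schema$type)) {
    allowed <- unlist(schema$type)
    ok <- typ %in% allowed ||
      (typ == "integer" && "number" %in% allowed) ||
      # an empty list is both an empty object and an empty array
      (typ %in% c("object", "array") && is.list(x) && length(x) == 0L &&
         any(c("object", "array") %in% allowed))
    if (!ok) {
      out <- c(out, schema_violation(
        path, paste0("expected type ", paste(allowed, collapse = "|"),
                     ", got ", typ)
      ))
      return(out)
    }
  }
  if (!is.null(schema$enum)) {
    if (!any(vapply(schema$enum, identical, TRUE, y = x))) {
      out <- c(out, schema_violation(path, "value not in enum"))
    }
  }
  if (!is.null(schema$minLength) && is.character(x) &&
      nchar(x) < schema$minLength) {
    out <- c(out, schema_violation(path, "string shorter than minLength"))
  }
  if (typ == "object") {
    for (req in unlist(schema$required)) {
      if (!req %in% names(x)) {
        out <- c(out, schema_violation(
          paste0(path, ".", req), "required property missing"
        ))
      }
    }
    for (nm in names(schema$properties)) {
      if (nm %in% names(x)) {
        out <- c(out, schema_check(
          x[[nm]], schema$properties[[nm]], paste0(path, ".", nm), root
        ))
      }
    }
    if (isFALSE(schema$additionalProperties)) {
      extra <- setdiff(names(x), names(schema$properties))
      for (nm in extra) {
        out <- c(out, schema_violation(
          paste0(path, ".", nm), "additional property not allowed"
        ))
      }
    }
  }
  if (typ == "array" || (is.list(x) && is.null(names(x)))) {
    if (!is.null(schema$minItems) && length(x) < schema$minItems) {
      out <- c(out, schema_violation(path, "fewer items than minItems"))
    }
    if (!is.null(schema$items)) {
      for (i in seq_along(x)) {
        out <- c(out, schema_check(
          x[[i]], schema$items, paste0(path, "[", i, "]"), root
        ))
      }
    }
  }
  out
}
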