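#' @importFrom rlang %||%
#' @import purrr
#' @importFrom tibble tibble as_tibble
NULL

# Canonical form of a terminology code: the tables we transcribe typeset codes
# with thousands separators and en-dashes ("85,354-9", "175,651,000"); strip
# separators and map any dash variant to ASCII hyphen.
normalize_code <- function(code) {
  stopifnot(is.character(code))
  out <- gsub(",", "", code, fixed = TRUE)
  out <- gsub("[‐‑‒–—−]", "-", out)
  trimws(out)
}

# ISO 8601 date or dateTime (what FHIR date/dateTime/instant fields carry).
is_iso_datetime <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) return(FALSE)
  re <- paste0(
    "^\\d{4}-\\d{2}-\\d{2}",
    "(T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:\\d{2})?)?$"
  )
  if (!grepl(re, x)) return(FALSE)
  !is.na(suppressWarnings(as.Date(substr(x, 1, 10))))
}

# Pad a date to a sortable dateTime key so "2024-01-01" < "2024-01-01T09:00".
datetime_key <- function(x) {
  if (is.null(x) || !nzchar(x)) return("")
  if (nchar(x) == 10) paste0(x, "T00:00:00") else sub("Z$", "+00:00", x)
}

# Syntactic UCUM check: printable ASCII, no whitespace, balanced brackets.
is_valid_ucum <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit)) return(FALSE)
  if (grepl("\\s", unit) || !grepl("^[\\x21-\\x7E]+$", unit, perl = TRUE)) {
    return(FALSE)
  }
  opens <- lengths(regmatches(unit, gregexpr("\\[", unit)))
  closes <- lengths(regmatches(unit, gregexpr("\\]", unit)))
  opens == closes
}

# RFC-4122-shaped random identifier for rendered cards/suggestions.
new_uuid <- function() {
  hex <- sample(c(0:9, letters[1:6]), 32, replace = TRUE)
  hex[13] <- "4"
  hex[17] <- sample(c("8", "9", "a", "b"), 1)
  paste0(
    paste(hex[1:8], collapse = ""), "-",
    paste(hex[9:12], collapse = ""), "-",
    paste(hex[13:16], collapse = ""), "-",
    paste(hex[17:20], collapse = ""), "-",
    paste(hex[21:32], collapse = "")
  )
}

cds_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "cdscards_error"))
}

# Run code with a private RNG stream, leaving the caller's stream untouched.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
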