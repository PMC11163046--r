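# Shared fixtures: all built in code, no files.

FIXED_NOW <- as.Date("2024-06-01")

test_pack <- local({
  pack <- NULL
  function() {
    if (is.null(pack)) pack <<- hypertension_pack()
    pack
  }
})

# A bundle holding a single quantity observation for a LOINC code.
single_obs_bundle <- function(code, value, unit, date = "2024-05-30",
                              id = "obs-1") {
  fhir_bundle(
    build_patient(),
    list(build_observation(id, "http://loinc.org", code, "obs", value, unit,
                           date))
  )
}

empty_bundle <- function() fhir_bundle(build_patient())

# Strip the random uuids so rendered output can be compared for determinism.
strip_uuids <- function(x) {
  if (is.list(x)) {
    x$uuid <- NULL
    return(lapply(x, strip_uuids))
  }
  x
}

# Independent Kleene three-valued logic oracle (truth-table lookup, written
# without reference to the engine's representation).
kleene_and <- function(a, b) {
  if (a == "false" || b == "false") return("false")
  if (a == "unknown" || b == "unknown") return("unknown")
  "true"
}
kleene_or <- function(a, b) {
  if (a == "true" || b == "true") return("true")
  if (a == "unknown" || b == "unknown") return("unknown")
  "false"
}
kleene_not <- function(a) {
  switch(a, true = "false", false = "true", unknown = "unknown")
}

# Independent interval-table oracle for BP grading: explicit lookup plus
# max severity, written without reference to the implementation.
bp_oracle <- function(sbp, dbp) {
  s_cat <- if (sbp >= 180) 5 else if (sbp >= 160) 4 else if (sbp >= 140) 3
    else if (sbp >= 130) 2 else 1
  d_cat <- if (dbp >= 110) 5 else if (dbp >= 100) 4 else if (dbp >= 90) 3
    else if (dbp >= 85) 2 else 1
  c("normal", "high-normal", "grade-1", "grade-2", "grade-3")[max(s_cat, d_cat)]
}

# Leaf expressions with known truth values over a fixed bundle: SBP 150 is
# present, eGFR is absent, so comparisons give true/false/unknown.
tv_fixture <- function() {
  bundle <- single_obs_bundle("8480-6", 150, "mm[Hg]")
  list(
    bundle = bundle,
    leaves = list(
      true = expr_compare("SBP", ">=", 140, "mm[Hg]"),
      false = expr_compare("SBP", ">=", 200, "mm[Hg]"),
      unknown = expr_compare("eGFR", "<", 60, "mL/min")
    )
  )
}
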