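# Expression engine: latest-value selection, leaf semantics, Kleene logic.

test_that("select_latest picks the maximal effective time", {
  reg <- test_pack()$registry
  b <- fhir_bundle(build_patient(), list(
    build_observation("sbp-a", "http://loinc.org", "8480-6", "SBP",
                      150, "mm[Hg]", "2024-01-01"),
    build_observation("sbp-b", "http://loinc.org", "8480-6", "SBP",
                      145, "mm[Hg]", "2024-02-01")
  ))
  m <- select_latest(b, resolve_concept(reg, "SBP"))
  expect_equal(m$value, 145)
  expect_identical(m$effective, "2024-02-01")
})

test_that("identical timestamps break ties by lexicographically greater id", {
  reg <- test_pack()$registry
  b <- fhir_bundle(build_patient(), list(
    build_observation("obs-a", "http://loinc.org", "8480-6", "SBP",
                      150, "mm[Hg]", "2024-01-01"),
    build_observation("obs-b", "http://loinc.org", "8480-6", "SBP",
                      145, "mm[Hg]", "2024-01-01")
  ))
  m <- select_latest(b, resolve_concept(reg, "SBP"))
  expect_identical(m$resource_id, "obs-b")
})

test_that("absent measurements select nothing and unit mismatches error", {
  reg <- test_pack()$registry
  expect_null(select_latest(empty_bundle(),
                            resolve_concept(reg, "SerumPotassium")))
  wrong_unit <- single_obs_bundle("2823-3", 5.0, "mg/dL")
  expect_error(select_latest(wrong_unit,
                             resolve_concept(reg, "SerumPotassium")),
               class = "unit_mismatch_error")
})

test_that("quantity comparisons honour strict and inclusive thresholds", {
  reg <- test_pack()$registry
  hr55 <- single_obs_bundle("8867-4", 55, "/min")
  expect_identical(evaluate(expr_compare("HeartRate", "<", 60, "/min"),
                            hr55, reg), "true")
  k_at_boundary <- single_obs_bundle("2823-3", 5.5, "mmol/L")
  expect_identical(evaluate(expr_compare("SerumPotassium", ">", 5.5, "mmol/L"),
                            k_at_boundary, reg), "false")
  expect_identical(evaluate(expr_compare("eGFR", "<", 60, "mL/min"),
                            empty_bundle(), reg), "unknown")
})

test_that("active_medications filters by status and ATC prefix", {
  b <- fhir_bundle(build_patient(), list(
    build_medication_statement("m1", "C07AB02", "metoprolol"),
    build_medication_statement("m2", "C07AB02", "metoprolol (stopped)",
                               status = "completed"),
    build_medication_statement("m3", "C03CA01", "furosemide")
  ))
  expect_length(active_medications(b, "C07"), 1)
  expect_identical(active_medications(b, "C07")[[1]]$id, "m1")
  expect_length(active_medications(b, "C09"), 0)
})

test_that("Kleene truth tables match the brute-force oracle exhaustively", {
  fx <- tv_fixture()
  reg <- test_pack()$registry
  states <- c("true", "false", "unknown")
  for (a in states) {
    expect_identical(evaluate(expr_not(fx$leaves[[a]]), fx$bundle, reg),
                     kleene_not(a), label = paste("not", a))
    for (b in states) {
      expect_identical(
        evaluate(expr_and(fx$leaves[[a]], fx$leaves[[b]]), fx$bundle, reg),
        kleene_and(a, b), label = paste(a, "and", b)
      )
      expect_identical(
        evaluate(expr_or(fx$leaves[[a]], fx$leaves[[b]]), fx$bundle, reg),
        kleene_or(a, b), label = paste(a, "or", b)
      )
      for (cc in states) {
        got <- evaluate(
          expr_or(expr_and(fx$leaves[[a]], fx$leaves[[b]]),
                  expr_not(fx$leaves[[cc]])),
          fx$bundle, reg
        )
        expect_identical(got, kleene_or(kleene_and(a, b), kleene_not(cc)),
                         label = paste("(", a, "&", b, ") | !", cc))
      }
    }
  }
})

test_that("workflow flags treat a never-recorded flag as false", {
  reg <- test_pack()$registry
  expect_identical(
    evaluate(expr_flag("SentHomeForConfirmation", FALSE), empty_bundle(), reg),
    "true"
  )
  flagged <- fhir_bundle(build_patient(), list(
    build_flag_observation("f1", "SentHomeForConfirmation", TRUE, "2024-05-01")
  ))
  expect_identical(
    evaluate(expr_flag("SentHomeForConfirmation", TRUE), flagged, reg),
    "true"
  )
  expect_identical(
    evaluate(expr_flag("SentHomeForConfirmation", FALSE), flagged, reg),
    "false"
  )
})

test_that("adding resources no referenced concept matches never changes a result", {
  reg <- test_pack()$registry
  expr <- expr_and(
    expr_compare("SBP", ">=", 140, "mm[Hg]"),
    expr_not(expr_has_diagnosis("HypertensionDiagnosis"))
  )
  set.seed(42)
  for (i in 1:25) {
    base_res <- list(build_bp_panel("bp1", sample(100:200, 1),
                                    sample(60:120, 1), "2024-05-01"))
    b0 <- fhir_bundle(build_patient(), base_res)
    noise <- list(
      build_observation("noise-k", "http://loinc.org", "2823-3", "K",
                        runif(1, 3, 7), "mmol/L", "2024-05-02"),
      build_observation("noise-cr", "http://loinc.org", "2160-0", "Cr",
                        runif(1, 0.5, 2), "mg/dL", "2024-05-03"),
      build_medication_statement("noise-med", "C10AA01", "statin")
    )
    b1 <- fhir_bundle(build_patient(), c(base_res, noise))
    expect_identical(evaluate(expr, b1, reg), evaluate(expr, b0, reg))
  }
})

test_that("evaluation is pure and expressions render compactly", {
  reg <- test_pack()$registry
  b <- single_obs_bundle("8480-6", 150, "mm[Hg]")
  expr <- expr_or(expr_compare("SBP", ">=", 140, "mm[Hg]"),
                  expr_compare("DBP", ">=", 90, "mm[Hg]"))
  r1 <- evaluate(expr, b, reg, now = FIXED_NOW)
  r2 <- evaluate(expr, b, reg, now = FIXED_NOW)
  expect_identical(r1, r2)
  expect_identical(format(expr),
                   "([SBP] >= 140 mm[Hg] OR [DBP] >= 90 mm[Hg])")
})

test_that("expression validation rejects unknown concepts and unit clashes", {
  reg <- test_pack()$registry
  expect_error(
    cdscards:::validate_expression(expr_compare("XYZ", "<", 1), reg),
    class = "concept_not_found"
  )
  expect_error(
    cdscards:::validate_expression(
      expr_compare("SBP", ">=", 140, unit = "kPa"), reg
    ),
    class = "expression_schema_error"
  )
})
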