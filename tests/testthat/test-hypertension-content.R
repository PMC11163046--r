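# Hypertension decision functions and golden-file checks against the
# published card tables.

test_that("BP categorization equals the interval-table oracle on the full grid", {
  grid <- expand.grid(sbp = 60:260, dbp = 30:160)
  got <- categorize_bp(grid$sbp, grid$dbp)
  want <- mapply(bp_oracle, grid$sbp, grid$dbp)
  expect_identical(got, unname(want))
})

test_that("published categorization examples hold and out-of-range input errors", {
  expect_identical(categorize_bp(145, 92), "grade-1")
  expect_identical(categorize_bp(128, 82), "normal")
  expect_identical(categorize_bp(135, 86), "high-normal")
  expect_identical(categorize_bp(120, 112), "grade-3")
  expect_error(categorize_bp(300, 80), class = "out_of_range_error")
  expect_error(categorize_bp(120, 20), class = "out_of_range_error")
})

test_that("the diagnosis flow follows the flowchart branches", {
  expect_identical(diagnosis_flow(FALSE, FALSE, 150, 95),
                   c("CARD SELF-MONITORING", "CARD FOLLOW-UP"))
  expect_identical(diagnosis_flow(FALSE, TRUE, 165, 70),
                   c("CARD GRADE-2", "CARD DIAGNOSE-HTN"))
  expect_identical(diagnosis_flow(FALSE, TRUE, 145, 95),
                   c("CARD 4", "CARD DIAGNOSE-HTN"))
  expect_identical(diagnosis_flow(FALSE, TRUE, 185, 70),
                   c("CARD GRADE-3", "CARD DIAGNOSE-HTN"))
  expect_identical(diagnosis_flow(FALSE, FALSE, 135, 80),
                   "CARD HIGH-NORMAL-BP")
  expect_identical(diagnosis_flow(FALSE, FALSE, 120, 70), "CARD NORMAL-BP")
  expect_identical(diagnosis_flow(TRUE, FALSE, 120, 70), character())
  expect_identical(diagnosis_flow(TRUE, TRUE, 190, 120), character())
})

test_that("autofill thresholds are strict: boundary values do not trigger", {
  reg <- test_pack()$registry
  expect_identical(
    autofill_findings(single_obs_bundle("8867-4", 55, "/min"), reg),
    "CARD BRADYCARDIA"
  )
  expect_identical(
    autofill_findings(single_obs_bundle("33914-3", 59, "mL/min"), reg),
    "CARD CKD"
  )
  boundary <- fhir_bundle(build_patient(), list(
    build_observation("o1", "http://loinc.org", "8867-4", "HR", 60, "/min",
                      "2024-05-30"),
    build_observation("o2", "http://loinc.org", "2823-3", "K", 5.5, "mmol/L",
                      "2024-05-30"),
    build_observation("o3", "http://loinc.org", "10230-1", "LVEF", 40, "%",
                      "2024-05-30"),
    build_observation("o4", "http://loinc.org", "33914-3", "eGFR", 60,
                      "mL/min", "2024-05-30")
  ))
  expect_identical(autofill_findings(boundary, reg), character())
  expect_identical(autofill_findings(empty_bundle(), reg), character())
})

test_that("beta-blocker contraindications cover asthma, A-V block and bradycardia", {
  reg <- test_pack()$registry
  asthma <- fhir_bundle(build_patient(), list(
    build_condition("c1", "http://hl7.org/fhir/sid/icd-10", "J45", "Asthma")
  ))
  expect_identical(medication_contraindications("C07", asthma, reg), "CARD 38")
  brady <- single_obs_bundle("8867-4", 55, "/min")
  expect_identical(medication_contraindications("C07", brady, reg), "CARD 38")
  block <- fhir_bundle(build_patient(), list(
    build_condition("c1", "http://hl7.org/fhir/sid/icd-10", "I44", "AV block")
  ))
  expect_identical(medication_contraindications("C07AB02", block, reg),
                   "CARD 38")
  expect_identical(medication_contraindications("C09", asthma, reg),
                   character())
  expect_identical(medication_contraindications("C07", empty_bundle(), reg),
                   character())
})

test_that("emergency referral uses strictly greater than 180/110", {
  expect_identical(emergency_referral_check(181, 70), "CARD EMERGENCY")
  expect_identical(emergency_referral_check(120, 111), "CARD EMERGENCY")
  expect_identical(emergency_referral_check(180, 110), character())
  expect_identical(emergency_referral_check(120, 70), character())
})

# --- golden-file reproduction of the published cards ------------------------

test_that("CARD 4 reproduces the published information card", {
  card <- render_card(test_pack()$cards[["CARD 4"]], now = FIXED_NOW)
  expect_identical(card$summary,
                   "Consider hypertension diagnosis with category Grade 1.")
  expect_length(card$suggestions, 0)
  expect_match(card$detail, "grade 1 \\(140")
  expect_match(card$source$citation, "Chapter 12.2 [pp. 40]", fixed = TRUE)
})

test_that("CARD 21 reproduces the appointment and creatinine lab order", {
  card <- render_card(test_pack()$cards[["CARD 21"]],
                      now = as.Date("2024-03-01"))
  expect_identical(card$summary, "Arrange a follow-up visit in 1 month.")
  actions <- card$suggestions[[1]]$actions
  expect_length(actions, 2)
  appt <- actions[[1]]$resource
  expect_identical(appt$resourceType, "Appointment")
  expect_identical(appt$status, "proposed")
  expect_identical(appt$start, "2024-04-01")
  sr <- actions[[2]]$resource
  expect_identical(sr$resourceType, "ServiceRequest")
  expect_identical(sr$code$coding[[1]]$code, "2160-0")
  expect_identical(sr$code$coding[[1]]$system, "http://loinc.org")
  expect_identical(sr$occurrenceDateTime, "2024-04-01")
  expect_identical(sr$category[[1]]$coding[[1]]$code, "lab-request")
  expect_identical(sr$intent, "proposal")
  expect_match(card$source$citation, "Chapter 12.3.1 [pp. 41 and 42]",
               fixed = TRUE)
})

test_that("CARD 18 reproduces the three resistant-hypertension actions", {
  card <- render_card(test_pack()$cards[["CARD 18"]],
                      now = as.Date("2024-03-01"))
  expect_identical(card$summary, "Management of resistant hypertension.")
  actions <- card$suggestions[[1]]$actions
  expect_length(actions, 3)
  selfmon <- actions[[1]]$resource
  expect_identical(selfmon$code$coding[[1]]$code, "85354-9")
  expect_identical(selfmon$category[[1]]$coding[[1]]$code, "patient-order")
  expect_identical(selfmon$occurrenceTiming$`repeat`$boundsPeriod$start,
                   "2024-03-01")
  expect_identical(selfmon$occurrenceTiming$`repeat`$boundsPeriod$end,
                   "2024-03-15")
  expect_identical(selfmon$occurrenceTiming$`repeat`$frequency, 2L)
  expect_identical(actions[[2]]$resource$start, "2024-03-15")
  referral <- actions[[3]]$resource
  expect_identical(referral$performerType$coding[[1]]$code, "175651000")
  expect_identical(referral$performerType$coding[[1]]$system,
                   "http://snomed.info/sct")
  expect_identical(referral$category[[1]]$coding[[1]]$code, "referral")
})

test_that("CARD 7 reproduces the two education-material actions with printed URLs", {
  card <- render_card(test_pack()$cards[["CARD 7"]], now = FIXED_NOW)
  actions <- card$suggestions[[1]]$actions
  expect_length(actions, 2)
  types <- vapply(actions, function(a) a$resource$resourceType, "")
  expect_identical(unique(types), "CommunicationRequest")
  urls <- vapply(actions,
                 function(a) a$resource$payload[[1]]$contentAttachment$url, "")
  expect_identical(urls, c(
    "https://www.nhsinform.scot/healthy-living/food-and-nutrition",
    "https://www.nhsinform.scot/healthy-living/keeping-active"
  ))
})

test_that("CARD 11 reproduces the systolic and diastolic goal targets", {
  card <- render_card(test_pack()$cards[["CARD 11"]],
                      now = as.Date("2024-03-01"))
  actions <- card$suggestions[[1]]$actions
  expect_length(actions, 2)
  sys_goal <- actions[[1]]$resource
  expect_identical(sys_goal$lifecycleStatus, "proposed")
  expect_identical(sys_goal$description$coding[[1]]$code, "135840009")
  tgt <- sys_goal$target[[1]]
  expect_identical(tgt$measure$coding[[1]]$code, "8480-6")
  expect_identical(tgt$detailRange$low$value, 130L)
  expect_identical(tgt$detailRange$high$value, 140L)
  expect_identical(tgt$dueDate, "2024-06-01") # {{Today + 3 months}}
  dia_goal <- actions[[2]]$resource
  dia_tgt <- dia_goal$target[[1]]
  expect_identical(dia_tgt$measure$coding[[1]]$code, "8482-4")
  expect_null(dia_tgt$detailRange$low)
  expect_identical(dia_tgt$detailRange$high$value, 80L)
})

test_that("CARD 31 and CARD 38 reproduce the medication pair", {
  pack <- test_pack()
  med <- render_card(pack$cards[["CARD 31"]], now = FIXED_NOW)
  expect_identical(
    med$summary,
    "Consider triple combination of ACEi/ARB, beta-blocker, CCB and diuretic by also checking possible contraindications."
  )
  res <- med$suggestions[[1]]$actions[[1]]$resource
  expect_identical(res$resourceType, "MedicationRequest")
  expect_identical(res$medicationCodeableConcept$coding[[1]]$code, "C07")
  expect_identical(res$medicationCodeableConcept$coding[[1]]$system,
                   "http://www.whocc.no/atc")
  warn_card <- render_card(pack$cards[["CARD 38"]], now = FIXED_NOW)
  expect_identical(warn_card$summary,
                   "Compelling side effects for Beta-Blockers.")
  expect_identical(warn_card$indicator, "warning")
  expect_length(warn_card$suggestions, 0)
  expect_match(warn_card$detail, "asthma or any high-grade sinoatrial")
})

test_that("the BP grid plot is a ggplot over the five categories", {
  p <- plot_bp_grid(sbp_range = 100:200, dbp_range = 60:120)
  expect_s3_class(p, "ggplot")
  expect_identical(levels(p$data$category),
                   c("normal", "high-normal", "grade-1", "grade-2", "grade-3"))
})
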